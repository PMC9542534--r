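#' Default infant-gut taxonomy used by the cohort simulator
#'
#' A small genus-level taxonomy of taxa commonly dominating the infant gut
#' during the first year of life (bifidobacteria, Bacteroides, bacilli,
#' clostridia, enterobacteria and typical reagent contaminants), with
#' class / order / family lineage and a baseline log-weight describing a
#' realistic early-life community composition.
#'
#' @param n_taxa number of taxa required. Up to the size of the built-in
#'   table, real taxa are returned; beyond it, synthetic genera
#'   (\code{Genus001} in \code{FamilyA} ...) are appended so that simulations
#'   with large taxon counts remain possible.
#' @return data.frame with columns \code{taxon}, \code{class}, \code{order},
#'   \code{family}, \code{genus}, \code{base_logw} (natural-log baseline
#'   community weight, arbitrary origin) and \code{trend} (per-timepoint
#'   shift of the taxon relative to the community-wide load growth; negative
#'   values mean the taxon loses community share with age).
#' @export
default_taxonomy <- function(n_taxa = NULL) {
  tab <- read.table(header = TRUE, sep = ",", strip.white = TRUE,
                    stringsAsFactors = FALSE, text = "
class,order,family,genus,base_logw,trend
Bacteroidia,Bacteroidales,Bacteroidaceae,Bacteroides,2.0,0.10
Bacteroidia,Bacteroidales,Rikenellaceae,Alistipes,-1.0,0.15
Bacteroidia,Bacteroidales,Porphyromonadaceae,Parabacteroides,0.0,0.10
Bacteroidia,Bacteroidales,Porphyromonadaceae,Paludibacter,-2.5,0.10
Bacteroidia,Bacteroidales,Prevotellaceae,Prevotella,-1.5,0.15
Actinobacteria,Bifidobacteriales,Bifidobacteriaceae,Bifidobacterium,3.0,0.00
Actinobacteria,Coriobacteriales,Coriobacteriaceae,Collinsella,-0.5,0.20
Actinobacteria,Actinomycetales,Actinomycetaceae,Actinomyces,-2.0,0.00
Actinobacteria,Actinomycetales,Micrococcaceae,Rothia,-2.5,-0.05
Actinobacteria,Actinomycetales,Streptomycetaceae,Streptomyces,-3.5,0.00
Bacilli,Bacillales,Staphylococcaceae,Staphylococcus,-0.5,-0.35
Bacilli,Bacillales,Bacillaceae,Bacillus,-3.0,0.00
Bacilli,Lactobacillales,Enterococcaceae,Enterococcus,-0.5,-0.15
Bacilli,Lactobacillales,Lactobacillaceae,Lactobacillus,-0.5,-0.05
Bacilli,Lactobacillales,Streptococcaceae,Streptococcus,1.0,-0.15
Clostridia,Clostridiales,Clostridiaceae,Clostridium,-0.5,0.15
Clostridia,Clostridiales,Lachnospiraceae,Blautia,0.0,0.30
Clostridia,Clostridiales,Lachnospiraceae,Roseburia,-1.5,0.35
Clostridia,Clostridiales,Ruminococcaceae,Faecalibacterium,-1.0,0.40
Clostridia,Clostridiales,Ruminococcaceae,Ruminococcus,-1.5,0.30
Clostridia,Clostridiales,Peptostreptococcaceae,Intestinibacter,-2.0,0.15
Clostridia,Clostridiales,Christensenellaceae,Christensenella,-3.0,0.20
Clostridia,Clostridiales,Peptoniphilaceae,Finegoldia,-2.5,-0.10
Negativicutes,Selenomonadales,Veillonellaceae,Veillonella,0.5,0.05
Negativicutes,Selenomonadales,Veillonellaceae,Megasphaera,-2.0,0.10
Negativicutes,Selenomonadales,Acidaminococcaceae,Phascolarctobacterium,-2.0,0.15
Gammaproteobacteria,Enterobacteriales,Enterobacteriaceae,Escherichia,1.5,-0.05
Gammaproteobacteria,Enterobacteriales,Enterobacteriaceae,Klebsiella,0.0,-0.10
Gammaproteobacteria,Enterobacteriales,Enterobacteriaceae,Enterobacter,-1.5,-0.10
Gammaproteobacteria,Pasteurellales,Pasteurellaceae,Haemophilus,-2.0,0.00
Betaproteobacteria,Burkholderiales,Alcaligenaceae,Achromobacter,-4.5,0.00
Betaproteobacteria,Burkholderiales,Burkholderiaceae,Ralstonia,-5.0,0.00
Verrucomicrobiae,Verrucomicrobiales,Verrucomicrobiaceae,Akkermansia,-2.0,0.25
Erysipelotrichia,Erysipelotrichales,Erysipelotrichaceae,Turicibacter,-2.5,0.10
")
  tab$taxon <- tab$genus
  if (!is.null(n_taxa)) {
    if (n_taxa <= nrow(tab)) {
      tab <- tab[seq_len(n_taxa), , drop = FALSE]
    } else {
      extra <- n_taxa - nrow(tab)
      idx <- seq_len(extra)
      fam <- sprintf("Family%02d", ((idx - 1) %/% 5) + 1)
      syn <- data.frame(
        class = "SynClassA", order = "SynOrderA", family = fam,
        genus = sprintf("Genus%03d", idx),
        base_logw = rep_len(c(-1, -1.5, -2, -2.5, -3), extra),
        trend = 0,
        stringsAsFactors = FALSE)
      syn$taxon <- syn$genus
      tab <- rbind(tab, syn)
    }
  }
  rownames(tab) <- tab$taxon
  tab[, c("taxon", "class", "order", "family", "genus", "base_logw", "trend")]
}

#' Default 16S rRNA gene copy-number table
#'
#' Family-level mean 16S copy numbers in the style of the rrnDB database,
#' covering the default taxonomy. Bifidobacteriaceae carry a low mean copy
#' number (3.5) and Clostridiales families a high one (5.5), the canonical
#' contrast driving copy-number correction of relative profiles.
#'
#' @return data.frame with columns \code{name}, \code{rank}, \code{mean16S}.
#' @export
default_copy_numbers <- function() {
  tab <- read.table(header = TRUE, sep = ",", strip.white = TRUE,
                    stringsAsFactors = FALSE, text = "
name,rank,mean16S
Bacteroidaceae,family,6.0
Rikenellaceae,family,3.5
Porphyromonadaceae,family,4.0
Prevotellaceae,family,3.5
Bifidobacteriaceae,family,3.5
Coriobacteriaceae,family,3.0
Actinomycetaceae,family,3.0
Micrococcaceae,family,2.5
Streptomycetaceae,family,6.0
Staphylococcaceae,family,5.5
Bacillaceae,family,8.0
Enterococcaceae,family,4.5
Lactobacillaceae,family,5.0
Streptococcaceae,family,5.5
Clostridiaceae,family,5.5
Lachnospiraceae,family,5.5
Ruminococcaceae,family,5.5
Peptostreptococcaceae,family,5.5
Christensenellaceae,family,5.5
Peptoniphilaceae,family,5.5
Veillonellaceae,family,5.0
Acidaminococcaceae,family,5.0
Enterobacteriaceae,family,7.0
Pasteurellaceae,family,6.0
Alcaligenaceae,family,3.0
Burkholderiaceae,family,4.0
Verrucomicrobiaceae,family,2.0
Erysipelotrichaceae,family,6.0
Clostridiales,order,5.5
Bifidobacteriales,order,3.5
")
  tab
}

#' Worked-example exposure records of a two-cohort infant study
#'
#' A 144-infant table of delivery mode, intrapartum antibiotic and dose count
#' reproducing the exposure distribution of a published Finnish two-cohort
#' infant study (93 infants exposed to intrapartum antibiotics across
#' vaginal, elective-cesarean and emergency-cesarean deliveries, plus 58
#' unexposed vaginally born infants; the 92-infant subset with qPCR-anchored
#' absolute profiles is flagged). Used as the worked example for
#' \code{\link{assign_study_group}} and in the test suite.
#'
#' @return data.frame with columns \code{infant_id}, \code{birth_mode}
#'   (\code{"VD"}, \code{"elective CS"}, \code{"emergency CS"}),
#'   \code{antibiotic}, \code{doses} (\code{"1"} or \code{"2+"}),
#'   \code{absolute_data} (logical; infant belongs to the qPCR subset).
#' @export
example_exposures <- function() {
  # rows: birth mode, antibiotic, dose category, n total, n with absolute data
  rows <- list(
    list("VD",           "penicillin",   "1",   4,  1),
    list("VD",           "penicillin",   "2+", 21, 12),
    list("VD",           "cefuroxime",   "1",   8,  3),
    list("VD",           "cefuroxime",   "2+",  5,  4),
    list("elective CS",  "cefuroxime",   "1",  13, 12),
    list("elective CS",  "cephalexin",   "1",   7,  7),
    list("elective CS",  "clindamycin",  "1",   1,  1),
    list("elective CS",  "metronidazole","1",   1,  1),
    list("elective CS",  "not reported", "1",   1,  1),
    list("emergency CS", "cefuroxime",   "1",  10, 10),
    list("emergency CS", "cefuroxime",   "2+",  1,  1),
    list("emergency CS", "cephalexin",   "1",   3,  3),
    list("emergency CS", "clindamycin",  "1",   2,  2),
    list("emergency CS", "clindamycin",  "2+",  2,  2),
    list("emergency CS", "penicillin",   "2+",  2,  1),
    list("emergency CS", "combination",  "1",   1,  1),
    list("emergency CS", "combination",  "2+",  4,  4),
    list("VD",           "none",         "0",  58, 26)
  )
  out <- do.call(rbind, lapply(rows, function(r) {
    n <- r[[4]]; n_abs <- r[[5]]
    data.frame(birth_mode = r[[1]], antibiotic = r[[2]], doses = r[[3]],
               absolute_data = c(rep(TRUE, n_abs), rep(FALSE, n - n_abs)),
               stringsAsFactors = FALSE)
  }))
  out$infant_id <- sprintf("I%03d", seq_len(nrow(out)))
  rownames(out) <- NULL
  out[, c("infant_id", "birth_mode", "antibiotic", "doses", "absolute_data")]
}
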
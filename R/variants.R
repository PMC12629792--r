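#' Filter annotated small variants
#'
#' Two filtering modes over VEP-style annotations:
#'
#' * `somatic`: removes likely germline variants — any population minor
#'   allele frequency (1000 Genomes, ESP, gnomAD) above 0.01 excludes the
#'   variant — and keeps only variants with Ensembl IMPACT `MODERATE` or
#'   `HIGH`.
#' * `ddr_germline`: restricted to the DNA-damage-repair genes BRCA1, BRCA2
#'   and PALB2; keeps variants with population MAF at or above 0.01 and
#'   IMPACT `HIGH`. This direction is deliberate (it selects the common
#'   germline variants of those genes); set `strict = FALSE` to flip to the
#'   conventional rare-variant filter (MAF <= 0.01).
#'
#' A missing population MAF is treated as unobserved in that population
#' (the variant is kept with respect to it) with a warning.
#'
#' @param variants Tibble with columns `gene`, `impact`, and population
#'   frequency columns `maf_1000g`, `maf_esp`, `maf_gnomad` (fractions,
#'   `NA` = unobserved).
#' @param mode `"somatic"` or `"ddr_germline"`.
#' @param strict In `ddr_germline` mode, keep the common-variant direction
#'   (default `TRUE`).
#' @return The retained rows of `variants`.
#' @export
filter_somatic_variants <- function(variants,
                                    mode = c("somatic", "ddr_germline"),
                                    strict = TRUE) {
  mode <- match.arg(mode)
  pop_cols <- c("maf_1000g", "maf_esp", "maf_gnomad")
  assert_cols(variants, c("gene", "impact", pop_cols), "variants")
  pop <- as.matrix(variants[, pop_cols])
  if (anyNA(pop)) {
    rlang::warn("missing population MAF treated as unobserved (kept for that population).")
  }
  if (mode == "somatic") {
    common <- apply(pop, 1, function(x) any(x > 0.01, na.rm = TRUE))
    keep <- !common & variants$impact %in% c("MODERATE", "HIGH")
  } else {
    ddr <- variants$gene %in% c("BRCA1", "BRCA2", "PALB2")
    if (strict) {
      freq_ok <- apply(pop, 1, function(x) any(x >= 0.01, na.rm = TRUE))
    } else {
      freq_ok <- !apply(pop, 1, function(x) any(x > 0.01, na.rm = TRUE))
    }
    keep <- ddr & freq_ok & variants$impact == "HIGH"
  }
  variants[keep, ]
}

#' Classify tumor mutational burden and microsatellite status
#'
#' TMB is dichotomized at the cohort median (strictly above = `"high"`; a
#' value equal to the median is `"low"`). Microsatellite status uses the
#' percentage of unstable loci: `"MSI"` at or above 20%, `"MSS"` below.
#'
#' @param tmb Mutations per megabase (>= 0).
#' @param msi_score Percent unstable microsatellite loci in `[0, 100]`.
#' @param tmb_median Median used for the TMB split; defaults to the median
#'   of `tmb` (recomputed per cohort).
#' @param msi_cutoff MSI percentage cutoff (default 20).
#' @return Tibble: `tmb`, `tmb_class`, `msi_score`, `msi_class`.
#' @export
classify_tmb_msi <- function(tmb, msi_score, tmb_median = median(tmb),
                             msi_cutoff = 20) {
  if (any(tmb < 0)) ck_abort("`tmb` must be >= 0.")
  if (any(msi_score < 0 | msi_score > 100)) {
    ck_abort("`msi_score` must be in [0, 100].")
  }
  tibble::tibble(
    tmb = tmb,
    tmb_class = ifelse(tmb > tmb_median, "high", "low"),
    msi_score = msi_score,
    msi_class = ifelse(msi_score >= msi_cutoff, "MSI", "MSS")
  )
}

#' Consensus KRAS genotype from tissue and ctDNA typing
#'
#' Harmonizes tumor DNA-sequencing and ctDNA G12 typing: agreeing calls
#' return that genotype; a single available call wins; disagreeing calls
#' return `"conflict"` (flagged for manual review, never silently
#' resolved); two missing calls return `"undetermined"`.
#'
#' @param tissue_call,ctdna_call Character vectors of genotype calls
#'   (`"G12D"`, `"G12V"`, `"G12R"`, `"WT"`), `NA` = missing.
#' @return Character vector of consensus genotypes.
#' @examples
#' consensus_kras(c("G12V", NA, "G12V"), c("G12V", "G12D", "G12D"))
#' @export
consensus_kras <- function(tissue_call, ctdna_call) {
  dplyr::case_when(
    is.na(tissue_call) & is.na(ctdna_call) ~ "undetermined",
    is.na(tissue_call) ~ ctdna_call,
    is.na(ctdna_call) ~ tissue_call,
    tissue_call == ctdna_call ~ tissue_call,
    .default = "conflict"
  )
}
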
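#' Parse a GMT gene-set file
#'
#' Standard GMT dialect: one set per line, tab-separated fields
#' `name`, `description`, then gene IDs. Duplicate genes within a set are
#' deduplicated with a warning.
#'
#' @param path Path to a `.gmt` file.
#' @return Named list of character gene-ID vectors; descriptions in the
#'   `descriptions` attribute.
#' @export
parse_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list()
  desc <- character()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3) {
      ck_abort(sprintf("malformed GMT line %d: fewer than 3 tab-separated fields.", i),
               class = "ctkinetics_schema_error")
    }
    genes <- fields[-(1:2)]
    if (anyDuplicated(genes)) {
      rlang::warn(sprintf("set '%s': duplicated gene IDs deduplicated.", fields[1]))
      genes <- unique(genes)
    }
    sets[[fields[1]]] <- genes
    desc[fields[1]] <- fields[2]
  }
  attr(sets, "descriptions") <- desc
  sets
}

# Column contracts per table; day columns are integers relative to first dose.
cohort_schema <- list(
  patients = c("patient_id", "genotype"),
  sld = c("patient_id", "day", "sld_mm"),
  ctdna = c("patient_id", "day", "maf_pct"),
  immune = c("patient_id", "day_label", "population", "frequency"),
  survival = c("patient_id", "os_days", "os_event", "pfs_days", "pfs_event")
)

check_unique_key <- function(df, key, name) {
  dup <- duplicated(df[, key])
  if (any(dup)) {
    ck_abort(sprintf("`%s`: duplicate key (%s) at row(s) %s.",
                     name, paste(key, collapse = ", "),
                     paste(head(which(dup), 5), collapse = ", ")),
             class = "ctkinetics_schema_error")
  }
}

#' Load and validate a cohort bundle from a directory of plain-text tables
#'
#' Reads the tables written by [write_cohort()] (`patients.csv`, `sld.csv`,
#' `ctdna.csv`, `immune.csv`, `survival.csv`, plus optional `truth.csv`,
#' `expression.tsv` and `genesets.gmt`), validates required columns,
#' numeric types and duplicate keys, and returns an in-memory bundle.
#' Missing optional tables are simply absent from the result.
#'
#' @param dir Directory containing the cohort files.
#' @return A list of class `ct_cohort` with the available components.
#' @export
load_cohort <- function(dir) {
  if (!dir.exists(dir)) ck_abort(sprintf("directory '%s' does not exist.", dir))
  bundle <- list()
  for (nm in names(cohort_schema)) {
    path <- file.path(dir, paste0(nm, ".csv"))
    if (!file.exists(path)) {
      if (nm %in% c("patients", "sld", "ctdna")) next  # optional stages skip
      next
    }
    df <- readr::read_csv(path, show_col_types = FALSE)
    assert_cols(df, cohort_schema[[nm]], paste0(nm, ".csv"))
    num_cols <- intersect(
      c("day", "sld_mm", "maf_pct", "frequency", "os_days", "os_event",
        "pfs_days", "pfs_event"),
      names(df)
    )
    for (col in num_cols) {
      if (!is.numeric(df[[col]])) {
        ck_abort(sprintf("`%s.csv`: column '%s' is not numeric.", nm, col),
                 class = "ctkinetics_schema_error")
      }
    }
    key <- switch(nm,
      patients = "patient_id",
      sld = c("patient_id", "day"),
      ctdna = c("patient_id", "day"),
      immune = c("patient_id", "day_label", "population"),
      survival = "patient_id"
    )
    check_unique_key(df, key, paste0(nm, ".csv"))
    bundle[[nm]] <- df
  }
  truth_path <- file.path(dir, "truth.csv")
  if (file.exists(truth_path)) {
    bundle$truth <- readr::read_csv(truth_path, show_col_types = FALSE)
  }
  expr_path <- file.path(dir, "expression.tsv")
  if (file.exists(expr_path)) {
    expr <- readr::read_tsv(expr_path, show_col_types = FALSE)
    m <- as.matrix(expr[, -1])
    rownames(m) <- expr[[1]]
    bundle$expression <- list(values = m, gene_ids = rownames(m),
                              sample_ids = colnames(m), scale = "vst")
  }
  gmt_path <- file.path(dir, "genesets.gmt")
  if (file.exists(gmt_path)) bundle$gene_sets <- parse_gmt(gmt_path)
  structure(bundle, class = "ct_cohort")
}
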
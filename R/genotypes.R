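#' Read a genotype table from a TSV/CSV file
#'
#' The canonical dialect is a tab-separated file whose first columns are the
#' individual metadata (`individual_id`, `cross_id`, `design`,
#' `f1_parent_sex`, `recurrent_population`, `maternal_population`, `sex`,
#' `stage`, `temperature_C`), followed by one column per marker holding
#' genotype codes `0` (homozygous for population P1), `1` (heterozygous),
#' `2` (homozygous for population P2) or `NA` (missing). Comma-separated
#' files are accepted (delimiter sniffed from the header). Marker columns
#' may be a subset of the panel; markers absent from the file are added as
#' all-missing columns. Marker columns not present in the panel are an
#' error.
#'
#' Population labels are dataset-level constants: code 0 always means
#' homozygous for the same population at every marker. No rows are dropped;
#' complete-case handling is deferred to the statistics functions.
#'
#' @param path Path to the file.
#' @param panel A marker panel tibble (see [marker_panel()]).
#' @return A tibble with the metadata columns followed by one integer
#'   column per panel marker, in panel order.
#' @export
read_genotype_table <- function(path, panel) {
  raw <- read_table_sniffed(path)
  missing_meta <- setdiff(META_COLS, names(raw))
  if (length(missing_meta) > 0) {
    abort(paste0(
      "genotype table is missing metadata column(s): ",
      paste(missing_meta, collapse = ", ")
    ))
  }
  marker_cols <- setdiff(names(raw), META_COLS)
  unknown <- setdiff(marker_cols, panel$marker_id)
  if (length(unknown) > 0) {
    abort(paste0(
      "genotype table has column(s) not in the marker panel: ",
      paste(unknown, collapse = ", ")
    ))
  }
  geno <- raw[META_COLS]
  geno$temperature_C <- suppressWarnings(as.numeric(geno$temperature_C))
  for (m in marker_cols) {
    v <- raw[[m]]
    bad <- which(!is.na(v) & !v %in% c("0", "1", "2"))
    if (length(bad) > 0) {
      abort(paste0(
        "invalid genotype code '", v[bad[1]], "' at row ", bad[1],
        ", marker column '", m, "' (must be 0, 1, 2 or NA)"
      ))
    }
    geno[[m]] <- as.integer(v)
  }
  for (m in setdiff(panel$marker_id, marker_cols)) {
    geno[[m]] <- NA_integer_
  }
  geno <- geno[c(META_COLS, panel$marker_id)]
  validate_genotype_meta(geno)
  geno
}

# Enum checks on the metadata columns; errors name the offending row/column.
validate_genotype_meta <- function(geno) {
  check_enum <- function(col, allowed, required = FALSE) {
    v <- geno[[col]]
    bad <- which((!is.na(v) & !v %in% allowed) | (required & is.na(v)))
    if (length(bad) > 0) {
      abort(paste0(
        "invalid value '", v[bad[1]], "' in column '", col, "' at row ",
        bad[1], " (allowed: ", paste(allowed, collapse = ", "),
        if (required) "; required" else "", ")"
      ))
    }
  }
  check_enum("design", DESIGNS)
  check_enum("f1_parent_sex", c("F", "M"))
  check_enum("recurrent_population", POPS)
  check_enum("maternal_population", POPS, required = TRUE)
  check_enum("sex", SEXES)
  check_enum("stage", STAGES)
  invisible(geno)
}

#' Write a genotype table to a TSV file
#'
#' Writes the canonical tab-separated dialect with `"NA"` for missing
#' values; the result round-trips through [read_genotype_table()] to an
#' identical table.
#'
#' @param genotypes A genotype tibble as produced by
#'   [read_genotype_table()] or [simulate_cross()].
#' @param path Output path.
#' @return Invisibly, `genotypes`.
#' @export
write_genotype_table <- function(genotypes, path) {
  readr::write_tsv(genotypes, path, na = "NA", progress = FALSE)
  invisible(genotypes)
}

# Marker columns of a genotype tibble (everything that is not metadata).
marker_cols <- function(genotypes) setdiff(names(genotypes), META_COLS)

# Apply an optional tidy-eval stratum predicate over the metadata.
apply_stratum <- function(genotypes, stratum) {
  q <- enquo(stratum)
  if (quo_is_null(q)) return(genotypes)
  keep <- eval_tidy(q, data = genotypes)
  if (!is.logical(keep)) abort("`stratum` must evaluate to a logical vector")
  genotypes[!is.na(keep) & keep, , drop = FALSE]
}

#' Marginal genotype counts at one marker
#'
#' Counts the three genotype classes and missing calls at a single marker,
#' optionally within a stratum of individuals. The four counts always sum
#' to the stratum size.
#'
#' @param genotypes Genotype tibble.
#' @param marker Marker id (must be a column of `genotypes`).
#' @param stratum Optional predicate over the metadata columns, evaluated
#'   with tidy evaluation (e.g. `sex == "F"`). Default: all individuals.
#' @return A one-row tibble with columns `marker_id`, `n0`, `n1`, `n2`,
#'   `n_missing`, `n` (non-missing total).
#' @examples
#' panel <- default_marker_panel()
#' sim <- simulate_cross(sim_config(panel, n_offspring = 50, seed = 1))
#' marginal_counts(sim, "3a")
#' marginal_counts(sim, "3a", stratum = sex == "F")
#' @export
marginal_counts <- function(genotypes, marker, stratum = NULL) {
  if (length(marker) != 1 || !marker %in% names(genotypes)) {
    abort(paste0("unknown marker: ", paste(marker, collapse = ", ")))
  }
  sub <- apply_stratum(genotypes, {{ stratum }})
  v <- sub[[marker]]
  tibble(
    marker_id = marker,
    n0 = sum(v == 0L, na.rm = TRUE),
    n1 = sum(v == 1L, na.rm = TRUE),
    n2 = sum(v == 2L, na.rm = TRUE),
    n_missing = sum(is.na(v)),
    n = sum(!is.na(v))
  )
}

# Extract a plain length-3 count vector from counts in any accepted form.
as_count_vector <- function(counts) {
  if (is.data.frame(counts)) {
    stopifnot(all(c("n0", "n1", "n2") %in% names(counts)), nrow(counts) == 1)
    counts <- c(counts$n0, counts$n1, counts$n2)
  }
  counts <- as.numeric(counts)
  if (any(!is.finite(counts)) || any(counts < 0)) {
    abort("genotype counts must be finite and nonnegative")
  }
  counts
}

#' Joint genotype counts at two or three markers
#'
#' Tabulates complete cases (individuals non-missing at *all* listed
#' markers) into a 3x3 or 3x3x3 contingency table of genotype classes.
#'
#' @inheritParams marginal_counts
#' @param markers Character vector of 2 or 3 distinct marker ids.
#' @return An integer array of dimension `c(3, 3)` or `c(3, 3, 3)` with
#'   dimnames `"0"`, `"1"`, `"2"` per axis and attribute `n` (the number of
#'   complete cases).
#' @export
joint_counts <- function(genotypes, markers, stratum = NULL) {
  if (anyDuplicated(markers)) {
    abort("`markers` must be distinct")
  }
  if (!length(markers) %in% c(2L, 3L)) {
    abort("`markers` must name exactly 2 or 3 markers")
  }
  missing_m <- setdiff(markers, names(genotypes))
  if (length(missing_m) > 0) {
    abort(paste0("unknown marker: ", paste(missing_m, collapse = ", ")))
  }
  sub <- apply_stratum(genotypes, {{ stratum }})
  calls <- lapply(markers, function(m) sub[[m]])
  complete <- Reduce(`&`, lapply(calls, function(v) !is.na(v)))
  lv <- lapply(calls, function(v) factor(v[complete], levels = 0:2))
  tab <- table(setNames(lv, markers))
  out <- array(as.integer(tab), dim = rep(3L, length(markers)),
               dimnames = rep(list(c("0", "1", "2")), length(markers)))
  attr(out, "n") <- sum(complete)
  out
}
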
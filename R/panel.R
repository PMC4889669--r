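#' @keywords internal
"_PACKAGE"

#' @importFrom rlang .data abort warn enquo quo_is_null eval_tidy %||%
#' @importFrom dplyr mutate filter select arrange group_by ungroup summarise
#'   bind_rows bind_cols across all_of left_join n
#' @importFrom tibble tibble as_tibble
#' @importFrom stats pchisq qchisq rpois runif rbinom dmultinom setNames
#'   plogis
NULL

# Metadata columns of the canonical genotype-table dialect, in file order.
META_COLS <- c(
  "individual_id", "cross_id", "design", "f1_parent_sex",
  "recurrent_population", "maternal_population", "sex", "stage",
  "temperature_C"
)

DESIGNS <- c("F2_INTERCROSS", "BACKCROSS", "BC2_INTERCROSS")
POPS <- c("P1", "P2")
SEXES <- c("F", "M", "UNKNOWN")
STAGES <- c("NAUPLIUS_D1", "NAUPLIUS_D2", "NAUPLIUS", "ADULT")

#' Construct and validate a marker panel
#'
#' A marker panel is a tibble with one row per marker, giving the marker
#' identifier, its chromosome label and its map position in centimorgans.
#' The panel fixes both the marker order of genotype tables and the
#' chromosome assignment used for linkage simulation and for enumeration of
#' inter-chromosomal tests.
#'
#' @param markers A data frame with columns `marker_id`, `chromosome`,
#'   `position_cM`. Row order is preserved and defines the panel order.
#' @return A tibble with columns `marker_id` (character), `chromosome`
#'   (character) and `position_cM` (double), validated so that marker ids
#'   are unique, positions are finite and nonnegative, and positions are
#'   nondecreasing within each chromosome in panel order.
#' @examples
#' marker_panel(data.frame(
#'   marker_id = c("1", "2a", "2b"),
#'   chromosome = c("1", "2", "2"),
#'   position_cM = c(0, 0, 20)
#' ))
#' @export
marker_panel <- function(markers) {
  req <- c("marker_id", "chromosome", "position_cM")
  missing_cols <- setdiff(req, names(markers))
  if (length(missing_cols) > 0) {
    abort(paste0(
      "marker panel is missing column(s): ",
      paste(missing_cols, collapse = ", ")
    ))
  }
  panel <- as_tibble(markers)[req]
  panel$marker_id <- as.character(panel$marker_id)
  panel$chromosome <- as.character(panel$chromosome)
  pos <- suppressWarnings(as.numeric(panel$position_cM))
  bad <- which(is.na(pos) | !is.finite(pos) | pos < 0)
  if (length(bad) > 0) {
    abort(paste0(
      "non-numeric or negative position_cM at row ", bad[1],
      " (marker '", panel$marker_id[bad[1]], "')"
    ))
  }
  panel$position_cM <- pos
  dup <- panel$marker_id[duplicated(panel$marker_id)]
  if (length(dup) > 0) {
    abort(paste0("duplicate marker_id: ", paste(unique(dup), collapse = ", ")))
  }
  for (ch in unique(panel$chromosome)) {
    p <- panel$position_cM[panel$chromosome == ch]
    if (is.unsorted(p)) {
      abort(paste0(
        "positions on chromosome '", ch,
        "' are not nondecreasing in panel order"
      ))
    }
  }
  panel
}

#' Read a marker panel from a TSV/CSV file
#'
#' The file must have a header with columns `marker_id`, `chromosome` and
#' `position_cM`. Tab is the canonical delimiter; comma is accepted and
#' detected from the header line.
#'
#' @param path Path to the file.
#' @return A validated marker panel tibble (see [marker_panel()]); marker
#'   order equals file order.
#' @export
read_marker_panel <- function(path) {
  raw <- read_table_sniffed(path)
  marker_panel(raw)
}

#' The default 25-marker, 12-chromosome panel
#'
#' A synthetic marker panel emulating a SNP panel used for genome-wide
#' scans of hybrid copepod crosses: 25 markers over 12 chromosomes with
#' per-chromosome marker counts (1, 3, 5, 3, 2, 2, 1, 4, 1, 1, 1, 1) and
#' marker labels `1`, `2a`-`2c`, `3a`-`3e`, `4a`-`4c`, `5a`-`5b`,
#' `6a`-`6b`, `7`, `8a`-`8d`, `9`, `10a`, `11`, `12`. Map positions are
#' arbitrary (markers evenly spaced within each chromosome) and are not
#' estimates from any dataset.
#'
#' @param spacing_cM Distance between adjacent markers on a chromosome, in
#'   centimorgans. Default 20.
#' @return A marker panel tibble.
#' @examples
#' default_marker_panel()
#' @export
default_marker_panel <- function(spacing_cM = 20) {
  counts <- c(1, 3, 5, 3, 2, 2, 1, 4, 1, 1, 1, 1)
  ids <- unlist(lapply(seq_along(counts), function(ch) {
    k <- counts[ch]
    if (k == 1 && !ch %in% 10) {
      as.character(ch)
    } else {
      paste0(ch, letters[seq_len(k)])
    }
  }))
  chrom <- rep(as.character(seq_along(counts)), counts)
  pos <- unlist(lapply(counts, function(k) spacing_cM * (seq_len(k) - 1)))
  marker_panel(tibble(
    marker_id = ids, chromosome = chrom, position_cM = pos
  ))
}

# Read a delimited text file, sniffing tab vs comma from the header line.
read_table_sniffed <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  header <- readLines(path, n = 1L)
  delim <- if (grepl("\t", header)) "\t" else ","
  readr::read_delim(
    path,
    delim = delim, na = "NA", show_col_types = FALSE, progress = FALSE,
    col_types = readr::cols(.default = readr::col_character())
  )
}
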
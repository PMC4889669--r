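# End-to-end orchestration: simulate or load -> scans -> thresholds ->
# TSV/JSON outputs, plus report assembly from a completed run directory.

#' Run the full analysis pipeline
#'
#' Executes an end-to-end run from a declarative configuration: load a
#' marker panel and genotype table from files *or* simulate a cross, run
#' the requested scans (single-locus, marker pairs, marker triples) within
#' the requested strata, and write all outputs (one TSV per scan, a
#' machine-readable JSON summary, and a plain-text log with per-stage
#' timings) into `out_dir`. The run is deterministic given the
#' configuration, including its seed.
#'
#' The configuration is a named list (or path to a YAML file with the same
#' structure) with elements:
#' \describe{
#'   \item{markers, genotypes}{Input file paths - mutually exclusive with
#'     `simulate`.}
#'   \item{simulate}{A list accepted by [sim_config()] minus the panel
#'     (e.g. `design`, `n_offspring`, plus optional `viability` /
#'     `sex` / `female_recombination` specifications); the default panel
#'     is used unless `markers` is also given.}
#'   \item{scans}{Character subset of `c("single", "pairs", "triples")`;
#'     default `"single"` and `"pairs"`.}
#'   \item{by}{Metadata columns defining strata (e.g. `c("sex")`);
#'     default none.}
#'   \item{family_alpha, df_policy, n_perm}{Statistical options with the
#'     package defaults.}
#'   \item{seed}{Required whenever any stochastic step (simulation or
#'     permutation) is enabled.}
#' }
#'
#' @param config Named list or path to a YAML config file.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the run summary as a named list (also written to
#'   `summary.json`): per scan the number of markers, tests, the
#'   Bonferroni alpha and the significant counts, plus per-stratum sample
#'   sizes and provenance (config hash, seed, package version).
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "run.log")
  log_lines <- character(0)
  log_stage <- function(stage, t0) {
    line <- sprintf("%s: %.2fs", stage, as.numeric(Sys.time()) - t0)
    log_lines <<- c(log_lines, line)
  }

  has_files <- !is.null(config$genotypes)
  has_sim <- !is.null(config$simulate)
  if (has_files == has_sim) {
    abort("config must give exactly one of {genotypes file, simulate block}")
  }

  t0 <- as.numeric(Sys.time())
  panel <- if (!is.null(config$markers)) {
    read_marker_panel(config$markers)
  } else {
    default_marker_panel()
  }
  if (has_files) {
    genotypes <- read_genotype_table(config$genotypes, panel)
  } else {
    sim <- config$simulate
    if (is.null(config$seed)) abort("`seed` is required for simulation")
    cfg <- sim_config(
      panel = panel,
      design = sim$design %||% "F2_INTERCROSS",
      n_offspring = sim$n_offspring %||% 100,
      seed = config$seed,
      f1_origin = sim$f1_origin %||% "P2",
      f1_parent_sex = sim$f1_parent_sex %||% NA,
      recurrent_population = sim$recurrent_population %||% NA,
      recombination = recombination_model(sim$female_recombination %||% 0),
      viability = parse_viability_spec(sim$viability),
      sex = parse_sex_spec(sim$sex)
    )
    genotypes <- simulate_cross(cfg)
    write_genotype_table(genotypes, file.path(out_dir, "genotypes.tsv"))
  }
  log_stage("load_or_simulate", t0)

  scans <- config$scans %||% c("single", "pairs")
  by <- config$by
  family_alpha <- config$family_alpha %||% 0.05
  df_policy <- config$df_policy %||% "reported_12"
  summary <- list(
    scans = list(),
    strata = stratum_sizes(genotypes, by),
    provenance = list(
      seed = config$seed,
      config_hash = config_hash(config),
      package_version = as.character(utils::packageVersion("dmiscan"))
    )
  )

  if ("single" %in% scans) {
    t0 <- as.numeric(Sys.time())
    res <- scan_single_locus(genotypes, panel, by = by,
                             family_alpha = family_alpha)
    readr::write_tsv(res, file.path(out_dir, "scan_single.tsv"), na = "NA")
    summary$scans$single <- list(
      n_markers = nrow(panel), n_tests = nrow(panel),
      alpha_bonf = bonferroni_alpha(family_alpha, nrow(panel)),
      n_significant_bonf = sum(res$significant, na.rm = TRUE),
      n_rows = nrow(res)
    )
    log_stage("scan_single", t0)
  }
  for (ord in c(2, 3)) {
    nm <- if (ord == 2) "pairs" else "triples"
    if (!nm %in% scans) next
    t0 <- as.numeric(Sys.time())
    res <- scan_interactions(
      genotypes, panel, order = ord, by = by, df_policy = df_policy,
      family_alpha = family_alpha,
      n_perm = config$n_perm,
      seed = if (!is.null(config$n_perm)) config$seed else NULL
    )
    readr::write_tsv(res, file.path(out_dir, paste0("scan_", nm, ".tsv")),
                     na = "NA")
    summary$scans[[nm]] <- list(
      n_markers = nrow(panel), n_tests = attr(res, "n_tests"),
      alpha_bonf = bonferroni_alpha(family_alpha, attr(res, "n_tests")),
      n_significant_bonf = sum(res$significant_bonf, na.rm = TRUE),
      n_significant_p001 = sum(res$significant_p001, na.rm = TRUE),
      n_rows = nrow(res)
    )
    log_stage(paste0("scan_", nm), t0)
  }

  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  writeLines(log_lines, log_path)
  invisible(summary)
}

stratum_sizes <- function(genotypes, by) {
  if (is.null(by)) return(list(all = nrow(genotypes)))
  grp <- split_by(genotypes, by)
  setNames(
    lapply(grp, function(g) nrow(g$data)),
    vapply(grp, function(g) paste(unlist(g$labels), collapse = "/"),
           character(1))
  )
}

config_hash <- function(config) {
  s <- paste(utils::capture.output(utils::str(config)), collapse = "\n")
  # small stable polynomial hash; avoids a digest dependency
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

parse_viability_spec <- function(spec) {
  if (is.null(spec)) return(viability_model())
  single <- lapply(spec$single_locus %||% list(), as.numeric)
  epi <- lapply(spec$epistatic %||% list(), function(e) {
    list(markers = e$markers, fitness = as.numeric(unlist(e$fitness)))
  })
  viability_model(single_locus = single, epistatic = epi)
}

parse_sex_spec <- function(spec) {
  if (is.null(spec)) return(sex_model())
  if (identical(spec$kind, "polygenic")) {
    sex_model("polygenic", effects = unlist(spec$effects))
  } else {
    sex_model("bernoulli_half")
  }
}

#' Assemble human-readable report tables from a completed run directory
#'
#' Reads the TSV outputs of [run_pipeline()] and returns (1) a per-marker
#' table ordered by chromosome and map position with relative viabilities,
#' standard errors and significance flags, and (2) interaction tables
#' restricted to tuples below the relaxed p < 0.001 threshold, with
#' Bonferroni survivors marked. Flags are taken verbatim from the TSVs; no
#' re-thresholding is done.
#'
#' @param out_dir A directory written by [run_pipeline()].
#' @return A list with elements `per_marker` (tibble or `NULL`),
#'   `pairs`, `triples` (tibbles or `NULL`) and `summary` (parsed JSON).
#' @export
report_run <- function(out_dir) {
  summary_path <- file.path(out_dir, "summary.json")
  if (!file.exists(summary_path)) {
    abort(paste0("not a completed run directory: ", out_dir))
  }
  read_scan <- function(name) {
    p <- file.path(out_dir, name)
    if (!file.exists(p)) return(NULL)
    readr::read_tsv(p, na = "NA", show_col_types = FALSE, progress = FALSE)
  }
  per_marker <- read_scan("scan_single.tsv")
  if (!is.null(per_marker)) {
    per_marker <- arrange(
      per_marker,
      as.numeric(.data$chromosome), .data$position_cM
    )
  }
  shortlist <- function(x) {
    if (is.null(x)) return(NULL)
    filter(x, !is.na(.data$significant_p001) & .data$significant_p001)
  }
  list(
    per_marker = per_marker,
    pairs = shortlist(read_scan("scan_pairs.tsv")),
    triples = shortlist(read_scan("scan_triples.tsv")),
    summary = jsonlite::read_json(summary_path)
  )
}
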
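# Single-locus statistics: goodness of fit to cross expectations, relative
# viabilities with delta-method standard errors, and between-group
# heterogeneity tests.

new_dmi_test <- function(statistic, df, p_value, method, n_used) {
  structure(
    list(
      statistic = statistic, df = df, p_value = p_value,
      method = method, n_used = n_used
    ),
    class = "dmi_test"
  )
}

#' @export
print.dmi_test <- function(x, ...) {
  cat(x$method, "\n")
  cat(
    sprintf(
      "chi2 = %.4g, df = %s, p = %.4g, n = %d\n",
      x$statistic, if (is.na(x$df)) "NA" else x$df, x$p_value, x$n_used
    )
  )
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a single test result
#'
#' @param x A `dmi_test` object.
#' @param ... Unused.
#' @return A one-row tibble with columns `statistic`, `df`, `p_value`,
#'   `method`, `n_used`.
#' @exportS3Method generics::tidy
tidy.dmi_test <- function(x, ...) {
  tibble(
    statistic = x$statistic, df = x$df, p_value = x$p_value,
    method = x$method, n_used = x$n_used
  )
}

#' Expected genotype-class proportions for a cross design
#'
#' An F2 intercross segregates 1:2:1 over (P1/P1, het, P2/P2); a backcross
#' to population P segregates 1:1 over (het, P/P) with the other homozygote
#' class structurally absent; a second-generation backcross intercross
#' between two carriers heterozygous at the focal chromosome segregates
#' 1:2:1 there.
#'
#' @param design One of `"F2_INTERCROSS"`, `"BACKCROSS"`,
#'   `"BC2_INTERCROSS"`.
#' @param recurrent_population For a backcross, `"P1"` or `"P2"`.
#' @return Numeric vector of length 3 over genotype codes (0, 1, 2),
#'   summing to 1.
#' @export
expected_genotype_ratio <- function(design, recurrent_population = NA) {
  switch(design,
    F2_INTERCROSS = c(0.25, 0.5, 0.25),
    BC2_INTERCROSS = c(0.25, 0.5, 0.25),
    BACKCROSS = {
      if (is.na(recurrent_population) ||
          !recurrent_population %in% POPS) {
        abort("BACKCROSS requires recurrent_population 'P1' or 'P2'")
      }
      if (recurrent_population == "P1") c(0.5, 0.5, 0) else c(0, 0.5, 0.5)
    },
    abort(paste0("unknown design: ", design))
  )
}

#' Pearson goodness-of-fit test of genotype counts against a Mendelian ratio
#'
#' Tests observed genotype-class counts against the class proportions
#' expected under a cross design (1:2:1 for an F2 intercross, 1:1 for a
#' backcross). Classes with expected proportion zero are structurally
#' excluded: they must have observed count zero (a genotype impossible
#' under the design), contribute nothing to the statistic, and reduce the
#' degrees of freedom, which are (number of classes with positive
#' expectation) - 1.
#'
#' @param counts Genotype counts: a numeric vector over classes, or a
#'   one-row tibble from [marginal_counts()] (columns `n0`, `n1`, `n2`).
#' @param expected_ratio Expected class proportions, same length as the
#'   counts; rescaled to sum to 1, so `c(1, 2, 1)` and `c(0.25, 0.5, 0.25)`
#'   are equivalent.
#' @return A `dmi_test` object (statistic, df, p_value, method, n_used).
#' @examples
#' gof_test(c(25, 50, 25), c(1, 2, 1)) # perfect fit: chi2 = 0
#' gof_test(c(8, 6, 0), c(1, 2, 1))
#' @export
gof_test <- function(counts, expected_ratio) {
  o <- as_count_vector(counts)
  r <- as.numeric(expected_ratio)
  if (length(r) != length(o)) {
    abort("`expected_ratio` must have the same length as the counts")
  }
  if (any(r < 0) || sum(r) <= 0) abort("`expected_ratio` must be nonnegative")
  r <- r / sum(r)
  n <- sum(o)
  if (n == 0) abort("no non-missing genotypes: N = 0")
  zero_exp <- r == 0
  if (any(o[zero_exp] > 0)) {
    abort("observed count in a class with zero expectation under the design")
  }
  o <- o[!zero_exp]
  r <- r[!zero_exp]
  e <- n * r
  stat <- sum((o - e)^2 / e)
  df <- length(o) - 1L
  if (df < 1) abort("fewer than two classes with positive expectation")
  new_dmi_test(stat, df, pchisq(stat, df, lower.tail = FALSE),
               "Pearson chi-squared goodness of fit", as.integer(n))
}

# All count vectors of length k summing to n (compositions), as a matrix
# with one row per outcome.
compositions <- function(n, k) {
  if (k == 1) return(matrix(n, ncol = 1))
  out <- lapply(0:n, function(i) {
    cbind(i, compositions(n - i, k - 1))
  })
  do.call(rbind, out)
}

#' Exact multinomial test of genotype counts against a Mendelian ratio
#'
#' Small-sample alternative to [gof_test()]: the p-value is the total
#' multinomial probability of all outcome vectors no more probable than the
#' observed one (the classical exact multinomial test). The `statistic`
#' slot carries -2 log of the observed outcome's probability and `df` is
#' reported as `NA` (no asymptotic reference distribution is used).
#'
#' @inheritParams gof_test
#' @param max_n Refuse totals above this cap (enumeration grows
#'   quadratically in N for three classes); default 200.
#' @return A `dmi_test` object with `method = "exact multinomial"`.
#' @examples
#' exact_multinomial_test(c(0, 0, 4), c(1, 2, 1))
#' @export
exact_multinomial_test <- function(counts, expected_ratio, max_n = 200) {
  o <- as_count_vector(counts)
  r <- as.numeric(expected_ratio)
  if (length(r) != length(o)) {
    abort("`expected_ratio` must have the same length as the counts")
  }
  r <- r / sum(r)
  n <- sum(o)
  if (n == 0) abort("no non-missing genotypes: N = 0")
  if (n > max_n) {
    abort(paste0(
      "N = ", n, " exceeds max_n = ", max_n,
      "; use gof_test() for large samples"
    ))
  }
  outcomes <- compositions(n, length(o))
  probs <- apply(outcomes, 1, dmultinom, prob = r)
  p_obs <- dmultinom(o, prob = r)
  # tolerance absorbs floating-point ties between equally probable outcomes
  p <- sum(probs[probs <= p_obs * (1 + 1e-07)])
  new_dmi_test(-2 * log(p_obs), NA_integer_, min(p, 1),
               "exact multinomial", as.integer(n))
}

#' Relative viability of homozygote classes against the heterozygote
#'
#' Estimates the survival of each homozygote genotype class relative to the
#' heterozygote class, scaled so that Mendelian segregation gives 1. Under
#' an expected homozygote:heterozygote ratio of e_hom:e_het, the estimate
#' is `w = (n_hom / e_hom) / (n_het / e_het)`; for the 1:2:1 F2 default
#' this is `w = 2 n_hom / n_het`. The standard error is the delta-method
#' SE of a ratio of independent counts, `w * sqrt(1/n_hom + 1/n_het)`,
#' reported as `NA` when the homozygote count is zero (the estimate itself
#' is then exactly 0).
#'
#' @inheritParams gof_test
#' @param expected_ratio Expected class proportions over (P1/P1, het,
#'   P2/P2); default the F2 1:2:1. The heterozygote class is always the
#'   reference. Homozygote classes with zero expectation get `NA`
#'   viability.
#' @return A one-row tibble with columns `w_p1`, `se_p1`, `w_p2`, `se_p2`,
#'   `n0`, `n1`, `n2`.
#' @examples
#' relative_viability(c(25, 50, 25)) # both 1
#' relative_viability(c(7, 8, 0))    # (1.75, 0)
#' relative_viability(c(3, 3, 1))    # (2.0, 0.67)
#' @export
relative_viability <- function(counts, expected_ratio = c(0.25, 0.5, 0.25)) {
  o <- as_count_vector(counts)
  if (length(o) != 3) abort("genotype counts must have 3 classes")
  r <- as.numeric(expected_ratio)
  r <- r / sum(r)
  if (o[2] < 1) abort("heterozygote count is 0: no reference class")
  one <- function(i) {
    if (r[i] == 0) return(c(NA_real_, NA_real_))
    w <- (o[i] / r[i]) / (o[2] / r[2])
    se <- if (o[i] == 0) NA_real_ else w * sqrt(1 / o[i] + 1 / o[2])
    c(w, se)
  }
  v1 <- one(1)
  v2 <- one(3)
  tibble(
    w_p1 = v1[1], se_p1 = v1[2], w_p2 = v2[1], se_p2 = v2[2],
    n0 = o[1], n1 = o[2], n2 = o[3]
  )
}

#' Heterogeneity of genotype ratios between groups
#'
#' Pearson contingency chi-squared test of a groups x genotype-classes
#' table, used e.g. to compare reciprocal crosses or the two sexes.
#' Genotype classes empty in every group (such as the absent homozygote
#' class of a backcross) are collapsed out before computing the statistic,
#' and the degrees of freedom are `(groups - 1) * (classes - 1)` after
#' collapse unless overridden.
#'
#' @param counts_by_group A list of count vectors / one-row count tibbles
#'   (one per group), or a matrix with one row per group.
#' @param df Optional degrees-of-freedom override replacing the textbook
#'   `(r - 1)(c - 1)`.
#' @return A `dmi_test` object.
#' @examples
#' heterogeneity_test(list(c(20, 40, 20), c(40, 40, 0)))
#' @export
heterogeneity_test <- function(counts_by_group, df = NULL) {
  if (is.matrix(counts_by_group)) {
    m <- counts_by_group
  } else {
    m <- do.call(rbind, lapply(counts_by_group, as_count_vector))
  }
  if (nrow(m) < 2) abort("need at least 2 groups")
  if (any(rowSums(m) == 0)) abort("a group has zero total count")
  m <- m[, colSums(m) > 0, drop = FALSE]
  if (ncol(m) < 2) abort("fewer than two non-empty genotype classes")
  n <- sum(m)
  e <- outer(rowSums(m), colSums(m)) / n
  stat <- sum((m - e)^2 / e)
  df_used <- if (is.null(df)) (nrow(m) - 1L) * (ncol(m) - 1L) else as.integer(df)
  new_dmi_test(stat, df_used, pchisq(stat, df_used, lower.tail = FALSE),
               "Pearson chi-squared heterogeneity", as.integer(n))
}

#' Single-locus segregation-distortion scan
#'
#' Runs the goodness-of-fit test and the relative-viability estimator at
#' every marker, optionally within strata defined by metadata columns, and
#' flags markers whose genotype ratios deviate from the design expectation
#' at the Bonferroni-corrected threshold for the number of markers (for a
#' 25-marker panel at family alpha 0.05 this is p < 0.002).
#'
#' Per-marker degeneracies (e.g. a marker with no non-missing calls in a
#' stratum, or no heterozygotes for the viability estimate) are recorded in
#' the `note` column of the affected row rather than aborting the scan.
#'
#' @param genotypes Genotype tibble.
#' @param panel Marker panel tibble.
#' @param by Character vector of metadata columns to stratify by (e.g.
#'   `c("cross_id", "sex")`); `NULL` analyses all individuals together.
#' @param expected_ratio Expected class proportions; default `NULL` derives
#'   them per stratum from the `design` and `recurrent_population` columns
#'   (which must then be constant within each stratum).
#' @param family_alpha Family-wise error rate for the Bonferroni flag;
#'   default 0.05.
#' @param method `"chisq"` (default) or `"exact"` (exact multinomial,
#'   small samples).
#' @return A tibble of class `dmi_scan_single` with one row per marker per
#'   stratum: `marker_id`, `chromosome`, `position_cM`, stratum columns,
#'   counts, `w_p1`/`se_p1`/`w_p2`/`se_p2`, `chi2`, `df`, `p`,
#'   `bonferroni_alpha`, `significant`, `method`, `note`.
#' @examples
#' panel <- default_marker_panel()
#' sim <- simulate_cross(sim_config(panel, n_offspring = 200, seed = 1))
#' scan_single_locus(sim, panel)
#' @export
scan_single_locus <- function(genotypes, panel, by = NULL,
                              expected_ratio = NULL, family_alpha = 0.05,
                              method = c("chisq", "exact")) {
  method <- match.arg(method)
  alpha_bonf <- bonferroni_alpha(family_alpha, nrow(panel))
  groups <- split_by(genotypes, by)
  rows <- purrr::map(groups, function(grp) {
    ratio <- expected_ratio %||% stratum_expected_ratio(grp$data)
    purrr::map(panel$marker_id, function(m) {
      scan_one_marker(grp$data, m, ratio, alpha_bonf, method, grp$labels)
    })
  })
  out <- bind_rows(purrr::flatten(rows))
  out <- left_join(out, panel, by = "marker_id")
  front <- c("marker_id", "chromosome", "position_cM", names(groups[[1]]$labels))
  out <- out[c(front, setdiff(names(out), front))]
  class(out) <- c("dmi_scan_single", class(out))
  attr(out, "family_alpha") <- family_alpha
  out
}

scan_one_marker <- function(data, m, ratio, alpha_bonf, method, labels) {
  counts <- marginal_counts(data, m)
  base <- counts[c("marker_id", "n0", "n1", "n2", "n_missing", "n")]
  if (length(labels) > 0) base <- bind_cols(as_tibble(labels), base)
  res <- tryCatch(
    {
      tst <- if (method == "chisq") {
        gof_test(counts, ratio)
      } else {
        exact_multinomial_test(counts, ratio)
      }
      viab <- tryCatch(
        relative_viability(counts, ratio),
        error = function(e) {
          tibble(w_p1 = NA_real_, se_p1 = NA_real_,
                 w_p2 = NA_real_, se_p2 = NA_real_)
        }
      )
      bind_cols(
        base,
        viab[c("w_p1", "se_p1", "w_p2", "se_p2")],
        tibble(
          chi2 = tst$statistic, df = tst$df, p = tst$p_value,
          bonferroni_alpha = alpha_bonf,
          significant = tst$p_value < alpha_bonf,
          method = tst$method, note = NA_character_
        )
      )
    },
    error = function(e) {
      bind_cols(
        base,
        tibble(
          w_p1 = NA_real_, se_p1 = NA_real_, w_p2 = NA_real_,
          se_p2 = NA_real_, chi2 = NA_real_, df = NA_integer_,
          p = NA_real_, bonferroni_alpha = alpha_bonf, significant = NA,
          method = method, note = conditionMessage(e)
        )
      )
    }
  )
  res
}

# Split a genotype tibble by metadata columns; returns a list of
# list(labels = named list, data = tibble). With by = NULL, one group with
# no label columns.
split_by <- function(genotypes, by) {
  if (is.null(by) || length(by) == 0) {
    return(list(list(labels = list(), data = genotypes)))
  }
  bad <- setdiff(by, META_COLS)
  if (length(bad) > 0) {
    abort(paste0("unknown stratification column(s): ",
                 paste(bad, collapse = ", ")))
  }
  keys <- genotypes[by]
  key_str <- do.call(paste, c(lapply(keys, as.character), sep = "\r"))
  idx <- split(seq_len(nrow(genotypes)), key_str)
  lapply(idx, function(i) {
    list(
      labels = as.list(genotypes[i[1], by, drop = FALSE]),
      data = genotypes[i, , drop = FALSE]
    )
  })
}

# Expected ratio for a stratum, derived from its design metadata; requires
# a single design (and recurrent population) within the stratum.
stratum_expected_ratio <- function(data) {
  d <- unique(data$design[!is.na(data$design)])
  if (length(d) != 1) {
    abort("stratum has no single cross design; supply expected_ratio")
  }
  rp <- unique(data$recurrent_population[!is.na(data$recurrent_population)])
  if (length(rp) > 1) {
    abort("stratum mixes recurrent populations; supply expected_ratio")
  }
  expected_genotype_ratio(d, if (length(rp) == 1) rp else NA)
}
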
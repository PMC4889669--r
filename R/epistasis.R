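# Two- and three-locus nonindependence statistics that absorb lower-order
# deviations, enumeration of inter-chromosomal test sets, and Bonferroni
# threshold bookkeeping.

#' Two-locus nonindependence test absorbing single-locus distortion
#'
#' Pearson chi-squared test of independence on a 3x3 joint genotype table,
#' with expected counts formed from the *observed* (possibly distorted)
#' marginals: `E_ij = row_i * col_j / n`. Using observed marginals is
#' exactly what "accounting for single-locus deviations first" means: a
#' marker pair whose joint distribution is the product of its distorted
#' marginals scores zero, so pure single-locus viability selection acting
#' independently at each locus does not inflate the statistic. Marginal
#' classes empty at a locus (e.g. the absent homozygote class of a
#' backcross) are collapsed out, reducing the degrees of freedom, which are
#' `(rows - 1) * (cols - 1)` after collapse (4 for a full 3x3).
#'
#' @param joint A 3x3 count table from [joint_counts()], or any numeric
#'   matrix of genotype-class counts.
#' @return A `dmi_test` object.
#' @examples
#' panel <- default_marker_panel()
#' sim <- simulate_cross(sim_config(panel, n_offspring = 300, seed = 1))
#' two_locus_test(joint_counts(sim, c("1", "7")))
#' @export
two_locus_test <- function(joint) {
  m <- unclass(as.matrix(joint))
  storage.mode(m) <- "double"
  if (any(m < 0) || any(!is.finite(m))) abort("joint counts must be nonnegative")
  n <- sum(m)
  if (n < 1) abort("no complete cases")
  m <- m[rowSums(m) > 0, colSums(m) > 0, drop = FALSE]
  if (nrow(m) < 2 || ncol(m) < 2) {
    abort("a locus has a single non-empty genotype class; statistic undefined")
  }
  e <- outer(rowSums(m), colSums(m)) / n
  stat <- sum((m - e)^2 / e)
  df <- (nrow(m) - 1L) * (ncol(m) - 1L)
  new_dmi_test(stat, df, pchisq(stat, df, lower.tail = FALSE),
               "two-locus nonindependence (observed-marginal chi-squared)",
               as.integer(n))
}

#' Iterative proportional fitting to all three pairwise margins
#'
#' Fits the no-three-way-interaction log-linear model to a 3x3x3 table:
#' the returned expected table is the (unique, maximum-entropy) nonnegative
#' table that reproduces all three observed two-way margins, obtained by
#' cycling IPF scaling updates over the AB, AC and BC margins until every
#' margin matches within `tol`. This is the expected table under "two-locus
#' structure only", so the residual chi-squared isolates genuinely
#' three-way dependence.
#'
#' @param joint A 3x3x3 count array from [joint_counts()].
#' @param tol Maximum absolute margin discrepancy at convergence; default
#'   1e-10.
#' @param max_iter Maximum IPF cycles before erroring; default 1000.
#' @return A 3x3x3 numeric array summing to `sum(joint)`, with attribute
#'   `iterations`.
#' @export
ipf_fit_no_three_way <- function(joint, tol = 1e-10, max_iter = 1000) {
  o <- array(as.numeric(joint), dim = dim(joint))
  if (length(dim(o)) != 3) abort("`joint` must be a 3-way array")
  if (tol <= 0) abort("`tol` must be positive")
  n <- sum(o)
  if (n < 1) abort("no complete cases")
  m12 <- apply(o, c(1, 2), sum)
  m13 <- apply(o, c(1, 3), sum)
  m23 <- apply(o, c(2, 3), sum)
  fit <- array(n / length(o), dim = dim(o))
  scale_margin <- function(fit, target, dims) {
    cur <- apply(fit, dims, sum)
    ratio <- ifelse(cur > 0, target / cur, 0)
    # expand ratio over the free dimension and rescale
    sweep_idx <- slice.index(fit, dims[1]) +
      dim(fit)[dims[1]] * (slice.index(fit, dims[2]) - 1)
    fit * array(ratio[sweep_idx], dim = dim(fit))
  }
  for (it in seq_len(max_iter)) {
    fit <- scale_margin(fit, m12, c(1, 2))
    fit <- scale_margin(fit, m13, c(1, 3))
    fit <- scale_margin(fit, m23, c(2, 3))
    disc <- max(
      abs(apply(fit, c(1, 2), sum) - m12),
      abs(apply(fit, c(1, 3), sum) - m13),
      abs(apply(fit, c(2, 3), sum) - m23)
    )
    if (disc <= tol) {
      attr(fit, "iterations") <- it
      return(fit)
    }
  }
  abort(paste0(
    "IPF did not converge in ", max_iter,
    " iterations; margin discrepancy = ", format(disc)
  ))
}

#' Three-locus nonindependence test absorbing two-locus structure
#'
#' Pearson chi-squared of the observed 3x3x3 table against the IPF fit to
#' all three pairwise margins ([ipf_fit_no_three_way()]), so that all
#' single-locus distortion and all pairwise nonindependence are absorbed
#' into the expected table and only irreducibly three-way dependence
#' contributes. Cells with expected count below `floor` (structural zeros
#' propagated from empty margins) are excluded from the sum, with one
#' degree of freedom removed per excluded cell; a warning is issued when
#' any retained expected cell is below 1 (sparse-table caution).
#'
#' Two degrees-of-freedom conventions are provided: `"reported_12"`
#' (default) uses 12 df, matching the convention under which published
#' critical values for this scan family (e.g. 42.4 at a Bonferroni-level
#' alpha over all inter-chromosomal triples) were computed; `"loglinear_8"`
#' uses the log-linear count `(3-1)^3 = 8` for the saturated-minus-pairwise
#' model. [permutation_p()] offers a df-free empirical alternative.
#'
#' @param joint A 3x3x3 count array from [joint_counts()].
#' @param df_policy `"reported_12"` or `"loglinear_8"`.
#' @param tol,max_iter Passed to [ipf_fit_no_three_way()].
#' @param floor Expected-count floor below which cells are treated as
#'   structural zeros; default 1e-12.
#' @return A `dmi_test` object.
#' @export
three_locus_test <- function(joint, df_policy = c("reported_12", "loglinear_8"),
                             tol = 1e-10, max_iter = 1000, floor = 1e-12) {
  df_policy <- match.arg(df_policy)
  e <- ipf_fit_no_three_way(joint, tol = tol, max_iter = max_iter)
  o <- array(as.numeric(joint), dim = dim(joint))
  keep <- e >= floor
  if (any(o[!keep] > 0)) {
    abort("observed count in a cell with (near-)zero fitted expectation")
  }
  if (any(e[keep] < 1)) {
    warn("sparse three-way table: some expected cells are below 1")
  }
  stat <- sum((o[keep] - e[keep])^2 / e[keep])
  base_df <- if (df_policy == "reported_12") 12L else 8L
  df <- max(1L, base_df - sum(!keep))
  new_dmi_test(
    stat, df, pchisq(stat, df, lower.tail = FALSE),
    paste0("three-locus nonindependence (IPF pairwise null, df ",
           df_policy, ")"),
    as.integer(sum(o))
  )
}

#' Permutation p-value for a two- or three-locus nonindependence statistic
#'
#' Empirical alternative to the asymptotic p-values: the genotype column of
#' the first listed marker is permuted among the individuals of the stratum
#' (preserving every marginal distribution while breaking joint structure),
#' the corresponding chi-squared statistic is recomputed for each
#' permutation, and the p-value is `(1 + #{permuted >= observed}) /
#' (1 + n_perm)`. This sidesteps the degrees-of-freedom convention of the
#' three-locus test entirely.
#'
#' @inheritParams joint_counts
#' @param n_perm Number of permutations (>= 1).
#' @param seed Integer seed (required: permutations are random).
#' @param df_policy Passed to [three_locus_test()] for the observed
#'   statistic's method label; the permutation p does not depend on it.
#' @return A `dmi_test` object whose `p_value` is the permutation p and
#'   whose `statistic`/`df` are those of the observed-data test.
#' @export
permutation_p <- function(genotypes, markers, stratum = NULL, n_perm = 999,
                          seed, df_policy = "reported_12") {
  if (missing(seed)) abort("`seed` is required")
  if (n_perm < 1) abort("`n_perm` must be >= 1")
  sub <- apply_stratum(genotypes, {{ stratum }})
  test_fun <- function(data) {
    jc <- joint_counts(data, markers)
    if (length(markers) == 2) {
      two_locus_test(jc)
    } else {
      suppressWarnings(three_locus_test(jc, df_policy = df_policy))
    }
  }
  obs <- test_fun(sub)
  set.seed(as.integer(seed))
  perm_stats <- vapply(seq_len(n_perm), function(i) {
    permuted <- sub
    permuted[[markers[1]]] <- sample(permuted[[markers[1]]])
    tryCatch(suppressWarnings(test_fun(permuted)$statistic),
             error = function(e) NA_real_)
  }, numeric(1))
  p <- (1 + sum(perm_stats >= obs$statistic, na.rm = TRUE)) / (1 + n_perm)
  new_dmi_test(obs$statistic, obs$df, p,
               paste0(obs$method, " + permutation p (n_perm = ", n_perm, ")"),
               obs$n_used)
}

#' Enumerate valid marker pairs or triples for interaction testing
#'
#' Lists the marker tuples entering an interaction scan. Under the default
#' `"inter_chromosomal_only"` policy, only tuples whose markers lie on
#' pairwise distinct chromosomes are tested, because linked markers are
#' expected to be nonindependent through linkage alone, not epistasis. For
#' the default 25-marker/12-chromosome panel this yields 276 pairs and
#' 1780 triples, the Bonferroni denominators of the scan.
#'
#' @param panel Marker panel tibble.
#' @param order 2 (pairs) or 3 (triples).
#' @param policy `"inter_chromosomal_only"` (default) or `"all"`.
#' @return A tibble with columns `marker1`, `marker2` (and `marker3`), one
#'   row per tuple, with attribute `n_tests` equal to the row count.
#' @examples
#' nrow(enumerate_tests(default_marker_panel(), 2)) # 276
#' nrow(enumerate_tests(default_marker_panel(), 3)) # 1780
#' @export
enumerate_tests <- function(panel, order = 2,
                            policy = c("inter_chromosomal_only", "all")) {
  policy <- match.arg(policy)
  if (!order %in% c(2, 3)) abort("`order` must be 2 or 3")
  m <- nrow(panel)
  if (m < order) {
    idx <- matrix(integer(0), nrow = order)
  } else {
    idx <- utils::combn(m, order)
  }
  if (policy == "inter_chromosomal_only" && ncol(idx) > 0) {
    chrom <- panel$chromosome
    keep <- apply(idx, 2, function(j) !anyDuplicated(chrom[j]))
    idx <- idx[, keep, drop = FALSE]
  }
  out <- as_tibble(setNames(
    lapply(seq_len(order), function(k) panel$marker_id[idx[k, ]]),
    paste0("marker", seq_len(order))
  ))
  attr(out, "n_tests") <- nrow(out)
  attr(out, "order") <- order
  attr(out, "policy") <- policy
  out
}

#' Bonferroni-corrected per-test significance threshold
#'
#' @param family_alpha Family-wise error rate (0 < alpha < 1).
#' @param n_tests Number of tests in the family (>= 1).
#' @return `family_alpha / n_tests`.
#' @examples
#' bonferroni_alpha(0.05, 25)   # 0.002
#' bonferroni_alpha(0.05, 276)  # 0.000181...
#' @export
bonferroni_alpha <- function(family_alpha, n_tests) {
  if (length(n_tests) != 1 || is.na(n_tests) || n_tests < 1) {
    abort("`n_tests` must be a positive integer")
  }
  if (family_alpha <= 0 || family_alpha >= 1) {
    abort("`family_alpha` must be in (0, 1)")
  }
  family_alpha / n_tests
}

#' Upper-tail chi-squared quantile and tail probability
#'
#' Thin validated wrappers over the chi-squared distribution used for
#' critical-value bookkeeping: `chi2_upper_quantile(p, df)` returns the
#' statistic value exceeded with probability `p`, and
#' `chi2_upper_tail(x, df)` the probability of exceeding `x`. The two are
#' mutual inverses.
#'
#' @param p Upper-tail probability in (0, 1).
#' @param x Statistic value (>= 0).
#' @param df Degrees of freedom (>= 1).
#' @return A numeric scalar.
#' @examples
#' chi2_upper_quantile(0.001, 12) # 32.909
#' chi2_upper_quantile(0.001, 4)  # 18.467
#' @export
chi2_upper_quantile <- function(p, df) {
  if (any(p <= 0 | p >= 1)) abort("`p` must be in (0, 1)")
  if (any(df < 1)) abort("`df` must be >= 1")
  qchisq(p, df, lower.tail = FALSE)
}

#' @rdname chi2_upper_quantile
#' @export
chi2_upper_tail <- function(x, df) {
  if (any(x < 0)) abort("`x` must be >= 0")
  if (any(df < 1)) abort("`df` must be >= 1")
  pchisq(x, df, lower.tail = FALSE)
}

#' Genome-wide interaction scan over marker pairs or triples
#'
#' Applies [two_locus_test()] or [three_locus_test()] to every enumerated
#' marker tuple ([enumerate_tests()]), per stratum, and annotates each row
#' with the Bonferroni threshold for the family of enumerated tests plus a
#' secondary relaxed flag at p < 0.001 (the conventional reporting cut for
#' suggestive interactions). Results are ranked by decreasing chi-squared
#' (ties broken lexicographically by marker ids); per-tuple degeneracies
#' (e.g. an empty marginal class) are recorded in `note` rather than
#' aborting.
#'
#' @inheritParams scan_single_locus
#' @param order 2 or 3.
#' @param policy Tuple policy, see [enumerate_tests()].
#' @param df_policy Passed to [three_locus_test()] for order 3.
#' @param n_perm If non-`NULL`, also compute permutation p-values with
#'   this many permutations (`seed` then required) - slow for full scans.
#' @param seed Integer seed for permutations.
#' @return A tibble of class `dmi_scan_interaction`: stratum columns,
#'   `locus1`, `locus2` (, `locus3`), `n_complete`, `chi2`, `df`, `p`,
#'   (`p_perm`,) `alpha_bonf`, `n_tests`, `significant_bonf`,
#'   `significant_p001`, `note`.
#' @examples
#' panel <- default_marker_panel()
#' sim <- simulate_cross(sim_config(panel, n_offspring = 200, seed = 1))
#' head(scan_interactions(sim, panel, order = 2))
#' @export
scan_interactions <- function(genotypes, panel, order = 2, by = NULL,
                              policy = "inter_chromosomal_only",
                              df_policy = "reported_12",
                              family_alpha = 0.05,
                              n_perm = NULL, seed = NULL) {
  tuples <- enumerate_tests(panel, order, policy)
  n_tests <- attr(tuples, "n_tests")
  if (n_tests == 0) abort("no testable tuples under this policy")
  alpha_bonf <- bonferroni_alpha(family_alpha, n_tests)
  if (!is.null(n_perm) && is.null(seed)) {
    abort("`seed` is required when `n_perm` is given")
  }
  groups <- split_by(genotypes, by)
  rows <- purrr::map(groups, function(grp) {
    purrr::map(seq_len(n_tests), function(i) {
      mk <- unlist(tuples[i, ], use.names = FALSE)
      scan_one_tuple(grp$data, mk, order, df_policy, alpha_bonf, n_tests,
                     n_perm, if (is.null(seed)) NULL else seed + i,
                     grp$labels)
    })
  })
  out <- bind_rows(purrr::flatten(rows))
  out <- arrange(
    out,
    dplyr::desc(dplyr::coalesce(.data$chi2, -Inf)),
    dplyr::across(all_of(paste0("locus", seq_len(order))))
  )
  class(out) <- c("dmi_scan_interaction", class(out))
  attr(out, "n_tests") <- n_tests
  attr(out, "family_alpha") <- family_alpha
  out
}

scan_one_tuple <- function(data, mk, order, df_policy, alpha_bonf, n_tests,
                           n_perm, seed, labels) {
  base <- as_tibble(setNames(as.list(mk), paste0("locus", seq_along(mk))))
  if (length(labels) > 0) base <- bind_cols(as_tibble(labels), base)
  res <- tryCatch(
    {
      jc <- joint_counts(data, mk)
      tst <- if (order == 2) {
        two_locus_test(jc)
      } else {
        suppressWarnings(three_locus_test(jc, df_policy = df_policy))
      }
      p_perm <- if (!is.null(n_perm)) {
        permutation_p(data, mk, n_perm = n_perm, seed = seed,
                      df_policy = df_policy)$p_value
      } else {
        NULL
      }
      row <- tibble(
        n_complete = tst$n_used, chi2 = tst$statistic, df = tst$df,
        p = tst$p_value
      )
      if (!is.null(p_perm)) row$p_perm <- p_perm
      bind_cols(base, row, tibble(
        alpha_bonf = alpha_bonf, n_tests = n_tests,
        significant_bonf = tst$p_value < alpha_bonf,
        significant_p001 = tst$p_value < 0.001,
        note = NA_character_
      ))
    },
    error = function(e) {
      bind_cols(base, tibble(
        n_complete = NA_integer_, chi2 = NA_real_, df = NA_integer_,
        p = NA_real_, alpha_bonf = alpha_bonf, n_tests = n_tests,
        significant_bonf = NA, significant_p001 = NA,
        note = conditionMessage(e)
      ))
    }
  )
  res
}
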
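# Shared fixtures and independent oracles for the test suite.
# All fixtures are built in code; nothing is read from disk except files
# the tests themselves write to tempdir().

# A minimal panel: k markers on given chromosomes at given positions.
tiny_panel <- function(chromosome, position_cM = NULL, marker_id = NULL) {
  k <- length(chromosome)
  marker_panel(data.frame(
    marker_id = marker_id %||% paste0("m", seq_len(k)),
    chromosome = as.character(chromosome),
    position_cM = position_cM %||% rep(0, k)
  ))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Build a genotype tibble by hand from a calls matrix (rows = individuals).
make_geno <- function(panel, calls, design = "F2_INTERCROSS",
                      maternal_population = "P2", sex = "F",
                      recurrent_population = NA_character_,
                      cross_id = "T1") {
  calls <- matrix(as.integer(calls), ncol = nrow(panel))
  n <- nrow(calls)
  meta <- tibble::tibble(
    individual_id = sprintf("i%03d", seq_len(n)),
    cross_id = rep(cross_id, n),
    design = rep(design, n),
    f1_parent_sex = rep(NA_character_, n),
    recurrent_population = rep(recurrent_population, n),
    maternal_population = rep(maternal_population, n),
    sex = rep(sex, n)[seq_len(n)],
    stage = rep("ADULT", n),
    temperature_C = rep(NA_real_, n)
  )
  geno <- tibble::as_tibble(as.data.frame(calls))
  names(geno) <- panel$marker_id
  dplyr::bind_cols(meta, geno)
}

# Independent oracle for the exact multinomial test: enumerate all k^N
# genotype sequences, aggregate to outcome vectors, and sum probabilities
# of outcomes no more probable than the observed one.
exact_multinomial_oracle <- function(counts, ratio) {
  k <- length(counts)
  n <- sum(counts)
  ratio <- ratio / sum(ratio)
  seqs <- as.matrix(expand.grid(rep(list(seq_len(k)), n)))
  prob_seq <- apply(seqs, 1, function(s) prod(ratio[s]))
  key <- apply(seqs, 1, function(s) paste(tabulate(s, k), collapse = ","))
  agg <- tapply(prob_seq, key, sum)
  p_obs <- agg[[paste(counts, collapse = ",")]]
  unname(sum(agg[agg <= p_obs * (1 + 1e-09)]))
}

# Elementary symmetric polynomials of per-chromosome marker counts: the
# closed-form count of inter-chromosomal pairs and triples.
esym2 <- function(c) (sum(c)^2 - sum(c^2)) / 2
esym3 <- function(c) (sum(c)^3 - 3 * sum(c) * sum(c^2) + 2 * sum(c^3)) / 6

# A 3x3x3 table exactly satisfying the no-three-way-interaction model:
# cell ~ exp(a_i + b_j + c_k + ab_ij + ac_ik + bc_jk).
no_three_way_table <- function(seed = 1, scale = 40) {
  set.seed(seed)
  a <- runif(3); b <- runif(3); cc <- runif(3)
  ab <- matrix(runif(9, -0.3, 0.3), 3)
  ac <- matrix(runif(9, -0.3, 0.3), 3)
  bc <- matrix(runif(9, -0.3, 0.3), 3)
  x <- array(0, c(3, 3, 3))
  for (i in 1:3) for (j in 1:3) for (k in 1:3) {
    x[i, j, k] <- exp(a[i] + b[j] + cc[k] + ab[i, j] + ac[i, k] + bc[j, k])
  }
  x * scale / mean(x)
}
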
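# Forward simulation of experimental hybrid crosses with sex-limited
# (achiasmatic) recombination and configurable viability selection.
#
# Genomes are stored as two haplotypes per individual: integer vectors over
# the panel's markers with values 1 (population P1 origin) or 2 (P2).
# The genotype code at a marker is (maternal + paternal origin) - 2, i.e.
# 0 = P1/P1, 1 = heterozygous, 2 = P2/P2.

#' Recombination model
#'
#' Crossovers are generated per chromosome as a Poisson process along the
#' genetic map (Haldane model, no interference): the crossover count is
#' Poisson with mean equal to the chromosome's marker span in Morgans, and
#' breakpoints are uniform on the span. Map distance d (cM) between two
#' markers then implies a recombination fraction `r = (1 - exp(-2d/100))/2`.
#' Female recombination is scaled by `female_recombination`, which defaults
#' to 0: females transmit every chromosome intact (achiasmatic meiosis, as
#' in *Tigriopus californicus*), so a female hybrid passes on whole
#' parental chromosomes.
#'
#' @param female_recombination Scaling factor in `[0, 1]` applied to the
#'   female map length; 0 (default) means no female recombination.
#' @return A list of class `dmi_recomb_model`.
#' @export
recombination_model <- function(female_recombination = 0) {
  if (female_recombination < 0 || female_recombination > 1) {
    abort("`female_recombination` must be in [0, 1]")
  }
  structure(
    list(map_function = "HALDANE",
         female_recombination = female_recombination),
    class = "dmi_recomb_model"
  )
}

#' Viability model
#'
#' Relative-fitness specification driving viability selection in the
#' simulator. Each component's fitness values are normalised by their
#' maximum, and the survival probability of a candidate offspring is the
#' product of all applicable components, so it always lies in `[0, 1]`.
#'
#' @param single_locus Named list: marker id -> numeric vector of length 3
#'   of relative fitnesses over genotype codes (0, 1, 2). E.g.
#'   `list("3d" = c(1, 1, 0))` makes the P2/P2 class at marker 3d lethal.
#' @param epistatic List of entries `list(markers = c(...), fitness = a)`
#'   where `a` is an array of dim `rep(3, k)` over the genotype codes of
#'   the k markers (k = 2 or 3). E.g. a table that is 0 only at
#'   `[3, 3]` makes the double P2/P2 homozygote lethal while each locus
#'   alone is neutral.
#' @return A list of class `dmi_viability_model`.
#' @export
viability_model <- function(single_locus = list(), epistatic = list()) {
  single_locus <- lapply(single_locus, function(w) {
    w <- as.numeric(w)
    if (length(w) != 3 || any(!is.finite(w)) || any(w < 0) || max(w) == 0) {
      abort("single-locus fitnesses must be 3 nonnegative values, not all 0")
    }
    w / max(w)
  })
  epistatic <- lapply(epistatic, function(e) {
    if (!is.list(e) || !all(c("markers", "fitness") %in% names(e))) {
      abort("epistatic entries must be list(markers = , fitness = )")
    }
    k <- length(e$markers)
    a <- array(as.numeric(e$fitness), dim = rep(3L, k))
    if (any(!is.finite(a)) || any(a < 0) || max(a) == 0) {
      abort("epistatic fitnesses must be nonnegative, not all 0")
    }
    list(markers = as.character(e$markers), fitness = a / max(a))
  })
  structure(list(single_locus = single_locus, epistatic = epistatic),
            class = "dmi_viability_model")
}

#' Sex-determination model
#'
#' `sex_model("bernoulli_half")` assigns sex by a fair coin. The polygenic
#' option exists so simulated data can exhibit genotype-sex associations
#' (sex-ratio-distorting loci): the probability of being female is
#' `plogis(sum(effect_i * (dosage_i - 1)))` where dosage is the P2-allele
#' count (the genotype code) at each listed marker.
#'
#' @param kind `"bernoulli_half"` or `"polygenic"`.
#' @param effects For `"polygenic"`, a named numeric vector of per-marker
#'   logit effects (names are marker ids).
#' @return A list of class `dmi_sex_model`.
#' @export
sex_model <- function(kind = c("bernoulli_half", "polygenic"),
                      effects = NULL) {
  kind <- match.arg(kind)
  if (kind == "polygenic") {
    if (is.null(effects) || is.null(names(effects))) {
      abort("polygenic sex model requires a named `effects` vector")
    }
    effects <- setNames(as.numeric(effects), names(effects))
  }
  structure(list(kind = kind, effects = effects), class = "dmi_sex_model")
}

#' Simulation configuration for one cross
#'
#' Bundles everything [simulate_cross()] needs. The design vocabulary
#' mirrors the experimental crosses the simulator emulates: an
#' `F2_INTERCROSS` mates two F1 hybrids; a `BACKCROSS` mates an F1 hybrid
#' (of sex `f1_parent_sex`) to a pure individual of `recurrent_population`.
#' `f1_origin` is the maternal population of the F1 parent(s), which fixes
#' the mtDNA background carried into the cross (an F1 from a P2-mother
#' cross transmits P2 mtDNA if female).
#'
#' @param panel Marker panel tibble.
#' @param design `"F2_INTERCROSS"` or `"BACKCROSS"`.
#' @param n_offspring Number of surviving offspring to produce.
#' @param seed Integer seed (required; the simulation is deterministic
#'   given the full configuration).
#' @param f1_origin Maternal population of the F1 parent(s): `"P1"` or
#'   `"P2"`. Default `"P2"`.
#' @param f1_parent_sex For a backcross, which parent is the F1 hybrid:
#'   `"F"` or `"M"`.
#' @param recurrent_population For a backcross, `"P1"` or `"P2"`.
#' @param recombination A [recombination_model()].
#' @param viability A [viability_model()].
#' @param sex A [sex_model()].
#' @param temperature_C Optional rearing temperature recorded in the
#'   metadata (no temperature-dependent mechanism is modelled).
#' @param stage Life stage recorded in the metadata; default `"ADULT"`.
#' @param cross_id Label recorded in the metadata; default derived from
#'   the design.
#' @param max_tries_per_offspring Rejection-sampling cap per surviving
#'   offspring before the viability model is declared degenerate; default
#'   1000.
#' @return A list of class `dmi_sim_config`.
#' @export
sim_config <- function(panel, design = c("F2_INTERCROSS", "BACKCROSS"),
                       n_offspring, seed, f1_origin = "P2",
                       f1_parent_sex = NA, recurrent_population = NA,
                       recombination = recombination_model(),
                       viability = viability_model(),
                       sex = sex_model(),
                       temperature_C = NA_real_, stage = "ADULT",
                       cross_id = NULL, max_tries_per_offspring = 1000) {
  design <- match.arg(design)
  if (missing(seed) || is.na(seed)) abort("`seed` is required")
  if (n_offspring < 0) abort("`n_offspring` must be >= 0")
  if (!f1_origin %in% POPS) abort("`f1_origin` must be 'P1' or 'P2'")
  if (design == "BACKCROSS") {
    if (!f1_parent_sex %in% c("F", "M")) {
      abort("BACKCROSS requires f1_parent_sex 'F' or 'M'")
    }
    if (!recurrent_population %in% POPS) {
      abort("BACKCROSS requires recurrent_population 'P1' or 'P2'")
    }
  }
  bad_markers <- setdiff(
    c(names(viability$single_locus),
      unlist(lapply(viability$epistatic, `[[`, "markers")),
      names(sex$effects)),
    panel$marker_id
  )
  if (length(bad_markers) > 0) {
    abort(paste0("model references markers not in panel: ",
                 paste(bad_markers, collapse = ", ")))
  }
  structure(
    list(
      panel = panel, design = design, n_offspring = n_offspring,
      seed = as.integer(seed), f1_origin = f1_origin,
      f1_parent_sex = f1_parent_sex,
      recurrent_population = recurrent_population,
      recombination = recombination, viability = viability, sex = sex,
      temperature_C = temperature_C, stage = stage,
      cross_id = cross_id %||% design,
      max_tries_per_offspring = max_tries_per_offspring
    ),
    class = "dmi_sim_config"
  )
}

# --- genome plumbing ---------------------------------------------------------

# Precompute per-chromosome marker index/position structure for a panel.
panel_chrom_info <- function(panel) {
  lapply(split(seq_len(nrow(panel)), panel$chromosome), function(i) {
    list(idx = i, pos = panel$position_cM[i],
         span_cM = max(panel$position_cM[i]) - min(panel$position_cM[i]))
  })
}

# A pure-population or F1 genome over the panel.
make_founder <- function(panel, pop, sex = "F") {
  m <- nrow(panel)
  h <- rep(if (pop == "P1") 1L else 2L, m)
  list(mat = h, pat = h, sex = sex, maternal_population = pop)
}

make_f1 <- function(panel, f1_origin, sex) {
  m <- nrow(panel)
  mat <- rep(if (f1_origin == "P1") 1L else 2L, m)
  pat <- rep(if (f1_origin == "P1") 2L else 1L, m)
  list(mat = mat, pat = pat, sex = sex, maternal_population = f1_origin)
}

# Generate n gametes from one parent: an n x n_markers integer matrix of
# population-origin labels. Vectorised over gametes; chromosomes with an
# effective map length of zero (or no recombination) reduce to a uniform
# choice of one parental haplotype, transmitted intact.
make_gametes <- function(parent, panel, model, n, chrom_info = NULL) {
  chrom_info <- chrom_info %||% panel_chrom_info(panel)
  m <- nrow(panel)
  out <- matrix(0L, nrow = n, ncol = m)
  strands <- rbind(parent$mat, parent$pat)
  factor <- if (parent$sex == "F") model$female_recombination else 1
  for (ci in chrom_info) {
    k <- length(ci$idx)
    lambda <- ci$span_cM / 100 * factor
    start <- sample.int(2L, n, replace = TRUE)
    if (lambda == 0 || k == 1 ||
        identical(parent$mat[ci$idx], parent$pat[ci$idx])) {
      out[, ci$idx] <- strands[start, ci$idx, drop = FALSE]
      next
    }
    nx <- rpois(n, lambda)
    plain <- nx == 0L
    if (any(plain)) {
      out[plain, ci$idx] <- strands[start[plain], ci$idx, drop = FALSE]
    }
    lo <- min(ci$pos)
    for (g in which(!plain)) {
      breaks <- sort(runif(nx[g], min = lo, max = lo + ci$span_cM))
      strand_at <- (start[g] - 1L + findInterval(ci$pos, breaks)) %% 2L + 1L
      out[g, ci$idx] <- strands[cbind(strand_at, ci$idx)]
    }
  }
  out
}

#' Draw a gamete (haplotype set) from a parent
#'
#' With no effective recombination (a female parent under the default
#' model, or a zero-length chromosome) each chromosome of the gamete is an
#' exact copy of one uniformly chosen parental haplotype. Otherwise the
#' crossover count per chromosome is Poisson with mean equal to the marker
#' span in Morgans, breakpoints are uniform on the span, and the strand is
#' swapped at each breakpoint starting from a uniformly chosen strand.
#'
#' @param parent A genome as produced by the simulator internals: a list
#'   with integer haplotypes `mat`, `pat` (values 1/2 over panel markers)
#'   and `sex`.
#' @param panel Marker panel tibble.
#' @param model A [recombination_model()].
#' @param n Number of gametes to draw.
#' @return An `n` x `nrow(panel)` integer matrix of population-of-origin
#'   labels (1 = P1, 2 = P2).
#' @export
make_gamete <- function(parent, panel, model = recombination_model(), n = 1) {
  make_gametes(parent, panel, model, n)
}

# Survival probabilities for a matrix of genotype codes (rows =
# individuals, columns = panel markers, values 0/1/2).
survival_prob <- function(geno, panel, viability) {
  p <- rep(1, nrow(geno))
  for (m in names(viability$single_locus)) {
    j <- match(m, panel$marker_id)
    p <- p * viability$single_locus[[m]][geno[, j] + 1L]
  }
  for (e in viability$epistatic) {
    j <- match(e$markers, panel$marker_id)
    idx <- geno[, j, drop = FALSE] + 1L
    p <- p * e$fitness[idx]
  }
  p
}

assign_sex_codes <- function(geno, panel, sexmod) {
  n <- nrow(geno)
  if (sexmod$kind == "bernoulli_half") {
    p_female <- rep(0.5, n)
  } else {
    lin <- rep(0, n)
    for (m in names(sexmod$effects)) {
      j <- match(m, panel$marker_id)
      lin <- lin + sexmod$effects[[m]] * (geno[, j] - 1)
    }
    p_female <- plogis(lin)
  }
  ifelse(runif(n) < p_female, "F", "M")
}

#' Assign sex to simulated offspring
#'
#' @param geno Integer matrix of genotype codes (individuals x markers,
#'   values 0/1/2) in panel order.
#' @param panel Marker panel tibble.
#' @param model A [sex_model()].
#' @param seed Optional integer seed.
#' @return Character vector of `"F"`/`"M"`.
#' @export
assign_sex <- function(geno, panel, model = sex_model(), seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  assign_sex_codes(geno, panel, model)
}

# Produce n surviving offspring genomes from two parents under a viability
# model, by batched rejection sampling. Returns list(mat=, pat=) matrices.
breed <- function(mother, father, config, chrom_info) {
  n <- config$n_offspring
  panel <- config$panel
  mat_keep <- matrix(0L, 0, nrow(panel))
  pat_keep <- matrix(0L, 0, nrow(panel))
  tries <- 0
  max_tries <- config$max_tries_per_offspring * max(n, 1)
  while (nrow(mat_keep) < n) {
    batch <- max(2 * (n - nrow(mat_keep)), 64)
    tries <- tries + batch
    if (tries > max_tries + batch) {
      abort(paste0(
        "viability model rejected ", tries, " candidates for ",
        n, " offspring; model is degenerate (all-zero survival?)"
      ))
    }
    egg <- make_gametes(mother, panel, config$recombination, batch, chrom_info)
    sperm <- make_gametes(father, panel, config$recombination, batch, chrom_info)
    geno <- egg + sperm - 2L
    surv <- runif(batch) < survival_prob(geno, panel, config$viability)
    mat_keep <- rbind(mat_keep, egg[surv, , drop = FALSE])
    pat_keep <- rbind(pat_keep, sperm[surv, , drop = FALSE])
  }
  list(mat = mat_keep[seq_len(n), , drop = FALSE],
       pat = pat_keep[seq_len(n), , drop = FALSE])
}

genomes_to_table <- function(off, config, maternal_population,
                             id_prefix = "ind") {
  panel <- config$panel
  geno <- off$mat + off$pat - 2L
  n <- nrow(geno)
  sexes <- if (n > 0) assign_sex_codes(geno, panel, config$sex) else character(0)
  meta <- tibble(
    individual_id = if (n > 0) sprintf("%s_%04d", id_prefix, seq_len(n)) else character(0),
    cross_id = rep(config$cross_id, n),
    design = rep(config$design, n),
    f1_parent_sex = rep(as.character(config$f1_parent_sex), n),
    recurrent_population = rep(as.character(config$recurrent_population), n),
    maternal_population = rep(maternal_population, n),
    sex = sexes,
    stage = rep(config$stage, n),
    temperature_C = rep(config$temperature_C, n)
  )
  calls <- as_tibble(setNames(
    lapply(seq_len(nrow(panel)), function(j) geno[, j]),
    panel$marker_id
  ))
  if (n == 0) {
    calls <- as_tibble(setNames(
      replicate(nrow(panel), integer(0), simplify = FALSE), panel$marker_id
    ))
  }
  bind_cols(meta, calls)
}

#' Simulate one experimental cross
#'
#' Forward-simulates the requested number of *surviving* offspring from an
#' F2 intercross (F1 female x F1 male) or a backcross (F1 hybrid x pure
#' recurrent individual), under the configured recombination, viability and
#' sex models. Candidate offspring are generated by drawing one gamete per
#' parent and survive with probability equal to their viability; rejection
#' sampling continues until `n_offspring` survivors are collected or the
#' per-offspring try cap is exceeded. The output is deterministic given
#' the configuration, including the seed.
#'
#' @param config A [sim_config()].
#' @return A genotype tibble in the canonical dialect (metadata columns
#'   plus one integer column per panel marker).
#' @examples
#' panel <- default_marker_panel()
#' f2 <- simulate_cross(sim_config(panel, n_offspring = 100, seed = 42))
#' bc <- simulate_cross(sim_config(
#'   panel, "BACKCROSS", n_offspring = 100, seed = 42,
#'   f1_parent_sex = "F", recurrent_population = "P2"
#' ))
#' @export
simulate_cross <- function(config) {
  stopifnot(inherits(config, "dmi_sim_config"))
  set.seed(config$seed)
  panel <- config$panel
  chrom_info <- panel_chrom_info(panel)
  if (config$design == "F2_INTERCROSS") {
    mother <- make_f1(panel, config$f1_origin, "F")
    father <- make_f1(panel, config$f1_origin, "M")
    maternal_population <- config$f1_origin
  } else {
    f1 <- make_f1(panel, config$f1_origin, config$f1_parent_sex)
    pure <- make_founder(
      panel, config$recurrent_population,
      sex = if (config$f1_parent_sex == "F") "M" else "F"
    )
    if (config$f1_parent_sex == "F") {
      mother <- f1; father <- pure
      maternal_population <- config$f1_origin
    } else {
      mother <- pure; father <- f1
      maternal_population <- config$recurrent_population
    }
  }
  off <- breed(mother, father, config, chrom_info)
  genomes_to_table(off, config, maternal_population,
                   id_prefix = config$cross_id)
}

#' Simulate the full eight-backcross panel
#'
#' Produces all eight backcross types: both F1 origins (F1 from a
#' P1-mother cross, F1 from a P2-mother cross) x F1 parent sex (female =
#' nonrecombinant, male = recombinant) x recurrent population (P1, P2),
#' each with its own derived seed. This is the design used to contrast
#' nonrecombinant and recombinant transmission of a whole chromosome.
#'
#' @param config A [sim_config()] serving as the template (panel, models,
#'   seed); its design fields are overridden per cross.
#' @param n_per_cross Surviving offspring per backcross.
#' @return A named list of eight genotype tibbles; names encode
#'   `F1<sex>(<origin>)x<recurrent>`, e.g. `"F1F(P2)xP2"`.
#' @export
simulate_backcross_panel <- function(config, n_per_cross) {
  combos <- expand.grid(
    f1_origin = POPS, f1_parent_sex = c("F", "M"),
    recurrent_population = POPS, stringsAsFactors = FALSE
  )
  out <- lapply(seq_len(nrow(combos)), function(i) {
    cb <- combos[i, ]
    label <- sprintf("F1%s(%s)x%s", cb$f1_parent_sex, cb$f1_origin,
                     cb$recurrent_population)
    cfg <- sim_config(
      panel = config$panel, design = "BACKCROSS",
      n_offspring = n_per_cross, seed = config$seed + i,
      f1_origin = cb$f1_origin, f1_parent_sex = cb$f1_parent_sex,
      recurrent_population = cb$recurrent_population,
      recombination = config$recombination, viability = config$viability,
      sex = config$sex, temperature_C = config$temperature_C,
      stage = config$stage, cross_id = label,
      max_tries_per_offspring = config$max_tries_per_offspring
    )
    simulate_cross(cfg)
  })
  names(out) <- vapply(seq_len(nrow(combos)), function(i) {
    cb <- combos[i, ]
    sprintf("F1%s(%s)x%s", cb$f1_parent_sex, cb$f1_origin,
            cb$recurrent_population)
  }, character(1))
  out
}

#' Simulate second-generation backcross intercross lines
#'
#' Emulates a multigeneration design probing one focal chromosome: F1
#' hybrid females are backcrossed to the recurrent population for two
#' generations, at each generation retaining only female parents
#' heterozygous at `selection_marker`; two retained second-generation
#' carriers (one female, one male) are then intercrossed, so the focal
#' chromosome segregates 1:2:1 in the final progeny while the genomic
#' background is predominantly the recurrent population. With no female
#' recombination, every retained female carrier is heterozygous across the
#' entire focal chromosome, not just at the marker. Lines in which no
#' heterozygous carrier of the required sex is found go extinct and are
#' dropped (counted in the `n_extinct` attribute).
#'
#' @param config A [sim_config()] template; `f1_origin` sets the F1
#'   females' origin and `recurrent_population` (default `"P1"`) the
#'   recurrent parent.
#' @param n_lines Number of lines to attempt.
#' @param selection_marker Marker id used to select heterozygous carriers.
#' @param n_brood Brood size per intermediate backcross generation;
#'   default 24.
#' @return A list of retained lines, each
#'   `list(parents = <2-row genotype tibble>, progeny = <genotype tibble>)`;
#'   attribute `n_extinct` counts dropped lines.
#' @export
simulate_bc2_intercross <- function(config, n_lines, selection_marker,
                                    n_brood = 24) {
  panel <- config$panel
  if (!selection_marker %in% panel$marker_id) {
    abort(paste0("unknown selection_marker: ", selection_marker))
  }
  sel_j <- match(selection_marker, panel$marker_id)
  recurrent <- if (is.na(config$recurrent_population)) "P1" else {
    config$recurrent_population
  }
  chrom_info <- panel_chrom_info(panel)
  set.seed(config$seed)
  line_seeds <- sample.int(.Machine$integer.max - 1L, n_lines)

  pick_het <- function(off, sex_wanted, geno_sex) {
    geno <- off$mat + off$pat - 2L
    ok <- which(geno[, sel_j] == 1L & geno_sex == sex_wanted)
    if (length(ok) == 0) return(NULL)
    i <- ok[1]
    list(mat = off$mat[i, ], pat = off$pat[i, ], sex = sex_wanted)
  }

  # Two generations of backcrossing to the recurrent population starting
  # from an F1 female, keeping a heterozygous female carrier after the
  # first generation and a heterozygous carrier of `final_sex` after the
  # second. NULL on extinction.
  bc2_carrier <- function(cfg, final_sex) {
    mother <- make_f1(panel, config$f1_origin, "F")
    for (gen in 1:2) {
      father <- make_founder(panel, recurrent, sex = "M")
      off <- breed(mother, father, cfg, chrom_info)
      geno <- off$mat + off$pat - 2L
      sexes <- assign_sex_codes(geno, panel, config$sex)
      wanted <- if (gen == 1) "F" else final_sex
      cand <- pick_het(off, wanted, sexes)
      if (is.null(cand)) return(NULL)
      if (gen == 1) {
        mother <- list(mat = cand$mat, pat = cand$pat, sex = "F",
                       maternal_population = recurrent)
      } else {
        return(list(mat = cand$mat, pat = cand$pat, sex = final_sex,
                    maternal_population = recurrent))
      }
    }
  }

  run_line <- function(seed) {
    set.seed(seed)
    cfg <- config
    cfg$n_offspring <- n_brood
    mother <- bc2_carrier(cfg, "F")
    if (is.null(mother)) return(NULL)
    father_final <- bc2_carrier(cfg, "M")
    if (is.null(father_final)) return(NULL)
    # final intercross between two focal-chromosome heterozygotes
    icfg <- sim_config(
      panel = panel, design = "F2_INTERCROSS",
      n_offspring = config$n_offspring, seed = seed + 1L,
      f1_origin = config$f1_origin,
      recombination = config$recombination,
      viability = config$viability, sex = config$sex,
      stage = config$stage, cross_id = "BC2_INTERCROSS",
      max_tries_per_offspring = config$max_tries_per_offspring
    )
    off_final <- breed(mother, father_final, icfg, chrom_info)
    cfg_final <- icfg
    cfg_final$design <- "BC2_INTERCROSS"
    cfg_final$recurrent_population <- recurrent
    progeny <- genomes_to_table(off_final, cfg_final, recurrent,
                                id_prefix = "bc2")
    parents <- genomes_to_table(
      list(mat = rbind(mother$mat, father_final$mat),
           pat = rbind(mother$pat, father_final$pat)),
      cfg_final, recurrent, id_prefix = "parent"
    )
    parents$sex <- c("F", "M")
    list(parents = parents, progeny = progeny)
  }

  lines <- lapply(line_seeds, run_line)
  kept <- lines[!vapply(lines, is.null, logical(1))]
  attr(kept, "n_extinct") <- sum(vapply(lines, is.null, logical(1)))
  kept
}
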
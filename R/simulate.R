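#' Describe a simulated population
#'
#' Populations form a forest: a population with no parents exists from
#' the simulation horizon; one parent means a clean split at
#' `split_generation` generations before present; two parents form an
#' admixed population whose founding gametes are drawn from parent A
#' with probability `admixture_fraction` and from parent B otherwise.
#'
#' @param name population label.
#' @param ne diploid effective size: a single number for a constant size,
#'   or a two-column object (generation before present, Ne) of
#'   breakpoints interpolated linearly and held constant beyond the ends.
#' @param parents character vector of 0, 1 or 2 parent population names.
#' @param admixture_fraction probability that a founding gamete comes
#'   from the first parent; required iff there are two parents.
#' @param split_generation generations before present at which the
#'   population is founded; required iff there is at least one parent.
#' @return an object of class `population_spec`.
#' @export
population_spec <- function(name, ne, parents = character(),
                            admixture_fraction = NULL,
                            split_generation = NULL) {
  if (is.null(dim(ne))) {
    if (length(ne) != 1L) stop("scalar or two-column ne expected")
    sched <- data.frame(generation = 0, ne = as.numeric(ne))
  } else {
    sched <- as.data.frame(ne)
    names(sched) <- c("generation", "ne")
    sched <- sched[order(sched$generation), , drop = FALSE]
  }
  if (any(sched$ne < 2)) stop("Ne must be >= 2 everywhere")
  n_par <- length(parents)
  if (n_par > 2L) stop("at most 2 parents")
  if (n_par == 2L) {
    if (is.null(admixture_fraction) || admixture_fraction <= 0 ||
        admixture_fraction > 1)
      stop("two-parent populations need admixture_fraction in (0,1]")
  } else if (!is.null(admixture_fraction)) {
    stop("admixture_fraction only meaningful with two parents")
  }
  if (n_par >= 1L && is.null(split_generation))
    stop("populations with parents need split_generation")
  if (n_par == 0L && !is.null(split_generation))
    stop("root populations have no split_generation")
  structure(list(name = name, ne_schedule = sched,
                 parents = as.character(parents),
                 admixture_fraction = admixture_fraction,
                 split_generation = split_generation),
            class = "population_spec")
}

#' Describe a hard selective sweep
#'
#' Additive fitness 1, 1 + s, 1 + 2s by genotype at the focal variant,
#' applied in the target populations from `start_generation` generations
#' before present until the present.
#'
#' @param pos_bp focal position; the nearest simulated variant is used.
#' @param s selection coefficient per generation, > 0.
#' @param start_generation generations before present when selection
#'   starts.
#' @param target_populations populations under selection.
#' @param chrom chromosome name, default `"1"`.
#' @param initial_freq optional frequency of the focal allele at
#'   `start_generation`: the allele is injected into the target
#'   populations at that moment (rounded up to at least one copy),
#'   emulating a young de-novo beneficial mutation and hence a hard,
#'   single-origin sweep. When `NULL` (default) selection acts on the
#'   standing variant at `pos_bp`, whose haplotype background is
#'   already mosaic — a soft, standing-variation sweep.
#' @return an object of class `sweep_spec`.
#' @export
sweep_spec <- function(pos_bp, s, start_generation, target_populations,
                       chrom = "1", initial_freq = NULL) {
  stopifnot(s > 0, start_generation >= 1, length(target_populations) >= 1)
  if (!is.null(initial_freq))
    stopifnot(initial_freq > 0, initial_freq < 1)
  structure(list(chrom = as.character(chrom), pos_bp = as.integer(pos_bp),
                 s = s, start_generation = as.integer(start_generation),
                 target_populations = as.character(target_populations),
                 initial_freq = initial_freq),
            class = "sweep_spec")
}

# populations ancestral to (or equal to) any of the given targets
ancestral_closure <- function(pops, targets) {
  out <- character()
  frontier <- targets
  while (length(frontier)) {
    out <- union(out, frontier)
    frontier <- setdiff(
      unlist(lapply(frontier, function(nm) pops[[nm]]$parents)), out)
  }
  out
}

#' Assemble a simulation configuration
#'
#' @param populations list of [population_spec()] objects.
#' @param sample_sizes named integer vector: diploids to sample per
#'   population at present; only named populations are output.
#' @param chrom_length_bp chromosome length, default 50 Mb.
#' @param n_variants segregating sites per chromosome, default 2000.
#' @param recomb_rate Morgans per bp, default 1e-8 (1 cM/Mb).
#' @param n_chrom number of independently evolved chromosomes, default 1.
#' @param sweeps list of [sweep_spec()] objects.
#' @param seed integer RNG seed.
#' @param horizon_generations simulated depth for root populations,
#'   default 2000.
#' @param init_freq_range bounds of the uniform initial allele-frequency
#'   spectrum, default `c(0.05, 0.95)`; the lower bound mimics the
#'   ascertainment of array panels toward common variants.
#' @param resample_until_established if `TRUE`, a reproduction step that
#'   loses a swept allele still present in the parents is redrawn, so
#'   sweeps condition on establishment; losses are reported in the truth
#'   record either way.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(populations, sample_sizes,
                       chrom_length_bp = 5e7, n_variants = 2000,
                       recomb_rate = 1e-8, n_chrom = 1L,
                       sweeps = list(), seed = 1L,
                       horizon_generations = 2000L,
                       init_freq_range = c(0.05, 0.95),
                       resample_until_established = FALSE) {
  stopifnot(recomb_rate > 0, n_variants >= 2, chrom_length_bp > n_variants,
            length(populations) >= 1, length(sample_sizes) >= 1)
  names(populations) <- vapply(populations, `[[`, "", "name")
  if (anyDuplicated(names(populations))) stop("duplicated population names")
  for (p in populations) {
    unknown <- setdiff(p$parents, names(populations))
    if (length(unknown))
      stop("population '", p$name, "' has unknown parent(s): ",
           paste(unknown, collapse = ", "))
    if (!is.null(p$split_generation) &&
        p$split_generation >= horizon_generations)
      stop("split_generation of '", p$name, "' outside the horizon")
  }
  unknown <- setdiff(names(sample_sizes), names(populations))
  if (length(unknown))
    stop("sample_sizes name unknown populations: ",
         paste(unknown, collapse = ", "))
  for (nm in names(sample_sizes)) {
    final_ne <- ne_at(populations[[nm]], 0)
    if (sample_sizes[[nm]] > final_ne)
      stop("sample size for '", nm, "' exceeds its final Ne (", final_ne, ")")
  }
  structure(list(populations = populations,
                 sample_sizes = sample_sizes,
                 chrom_length_bp = as.integer(chrom_length_bp),
                 n_variants = as.integer(n_variants),
                 recomb_rate = recomb_rate,
                 n_chrom = as.integer(n_chrom),
                 sweeps = sweeps, seed = as.integer(seed),
                 horizon_generations = as.integer(horizon_generations),
                 init_freq_range = init_freq_range,
                 resample_until_established = isTRUE(resample_until_established)),
            class = "sim_config")
}

ne_at <- function(pop_spec, t) {
  sched <- pop_spec$ne_schedule
  if (nrow(sched) == 1L) return(max(2L, as.integer(round(sched$ne))))
  v <- stats::approx(sched$generation, sched$ne, xout = t, rule = 2)$y
  max(2L, as.integer(round(v)))
}

#' Closed-form heterozygosity decay under drift
#'
#' Expected heterozygosity after `generations` generations of drift in a
#' diploid Wright-Fisher population of effective size `ne`:
#' `h0 * (1 - 1/(2 ne))^generations`. Serves as the analytic oracle for
#' the simulator.
#'
#' @param ne diploid effective size (`Inf` allowed).
#' @param generations number of generations, >= 0.
#' @param h0 initial heterozygosity.
#' @return expected heterozygosity.
#' @export
expected_het_decay <- function(ne, generations, h0) {
  stopifnot(ne >= 2, generations >= 0)
  if (!is.finite(ne)) return(h0)
  h0 * (1 - 1 / (2 * ne))^generations
}

# Draw k gametes from a diploid pool. H is loci x haplotypes (columns
# 2i-1, 2i are one diploid); w optional per-diploid fitness weights.
pool_gametes <- function(H, posM, Lm, k, w = NULL) {
  n_par <- ncol(H) %/% 2L
  pick <- sample.int(n_par, k, replace = TRUE, prob = w)
  ncx <- stats::rpois(k, Lm)
  first <- sample.int(2L, k, replace = TRUE) - 1L   # 0 or 1
  out <- matrix(0L, nrow(H), k)
  simple <- ncx == 0L
  if (any(simple))
    out[, simple] <- H[, 2L * pick[simple] - 1L + first[simple],
                       drop = FALSE]
  for (g in which(!simple)) {
    cuts <- sort(stats::runif(ncx[g], 0, Lm))
    phase <- (findInterval(posM, cuts) + first[g]) %% 2L
    a <- H[, 2L * pick[g] - 1L]
    sel <- phase == 1L
    a[sel] <- H[sel, 2L * pick[g]]
    out[, g] <- a
  }
  out
}

sweep_weights <- function(H, focal, s) {
  g <- H[focal, c(TRUE, FALSE)] + H[focal, c(FALSE, TRUE)]
  1 + s * g
}

# One chromosome's forward simulation. Returns final pools and
# bookkeeping; everything uses the caller's RNG stream.
simulate_chrom <- function(config, chrom_name) {
  pops <- config$populations
  horizon <- config$horizon_generations
  L <- config$n_variants
  pos <- sort(sample.int(config$chrom_length_bp, L))
  posM <- pos * config$recomb_rate
  Lm <- config$chrom_length_bp * config$recomb_rate
  p0 <- stats::runif(L, config$init_freq_range[1], config$init_freq_range[2])

  sweeps <- Filter(function(sw) sw$chrom == chrom_name, config$sweeps)
  sweeps <- lapply(sweeps, function(sw) {
    sw$focal <- which.min(abs(pos - sw$pos_bp))
    sw$guard <- ancestral_closure(pops, sw$target_populations)
    # injected alleles do not exist before their sweep starts
    if (!is.null(sw$initial_freq)) p0[sw$focal] <<- 0
    sw
  })

  birth <- vapply(pops, function(p)
    if (length(p$parents)) p$split_generation else horizon, 0)
  kids_split <- vapply(names(pops), function(nm) {
    ks <- vapply(pops, function(p)
      if (nm %in% p$parents) p$split_generation else NA_real_, 0)
    if (all(is.na(ks))) Inf else min(ks, na.rm = TRUE)
  }, 0)
  last_need <- stats::setNames(
    ifelse(names(pops) %in% names(config$sample_sizes), 0, kids_split),
    names(pops))
  if (any(!is.finite(last_need)))
    stop("population(s) neither sampled nor ancestral to a sampled one: ",
         paste(names(pops)[!is.finite(last_need)], collapse = ", "))

  state <- list()
  founder_freq <- list()
  for (nm in names(pops)[birth == horizon]) {
    n0 <- ne_at(pops[[nm]], horizon)
    state[[nm]] <- matrix(stats::rbinom(L * 2L * n0, 1L, p0), L, 2L * n0)
    founder_freq[[nm]] <- rowMeans(state[[nm]])
  }

  traj <- list()
  sweep_log <- list()
  n_redraws <- 0L

  reproduce <- function(nm, t_next, HP) {
    active <- Filter(function(sw)
      nm %in% sw$target_populations && t_next < sw$start_generation, sweeps)
    guard <- if (config$resample_until_established)
      Filter(function(sw) nm %in% sw$guard, sweeps) else list()
    n_out <- ne_at(pops[[nm]], t_next)
    k <- 2L * n_out
    if (!length(active) && !length(guard))
      return(pool_gametes(HP, posM, Lm, k))
    w <- NULL
    if (length(active)) {
      w <- rep(1, ncol(HP) %/% 2L)
      for (sw in active) w <- w * sweep_weights(HP, sw$focal, sw$s)
    }
    parent_has <- vapply(guard, function(sw) sum(HP[sw$focal, ]) > 0L, TRUE)
    out <- NULL
    for (attempt in seq_len(100L)) {
      out <- pool_gametes(HP, posM, Lm, k, w)
      if (!length(guard)) return(out)
      lost <- vapply(guard, function(sw) sum(out[sw$focal, ]) == 0L, TRUE)
      if (!any(lost & parent_has)) return(out)
      n_redraws <<- n_redraws + 1L
    }
    out
  }

  for (t in seq(horizon, 1L)) {
    t_next <- t - 1L
    # de-novo sweep alleles appear in the targets at sweep start
    for (sw in sweeps) {
      if (is.null(sw$initial_freq) || t != sw$start_generation) next
      for (nm in intersect(sw$target_populations, names(state))) {
        nh <- ncol(state[[nm]])
        k <- max(1L, round(nh * sw$initial_freq))
        state[[nm]][sw$focal, ] <- 0L
        state[[nm]][sw$focal, sample.int(nh, k)] <- 1L
      }
    }
    # founding events: children whose split_generation == t
    for (nm in names(pops)[birth == t & birth < horizon]) {
      p <- pops[[nm]]
      n_out <- ne_at(p, t_next)
      k <- 2L * n_out
      if (length(p$parents) == 1L) {
        state[[nm]] <- reproduce(nm, t_next, state[[p$parents[1]]])
      } else {
        HA <- state[[p$parents[1]]]
        HB <- state[[p$parents[2]]]
        alpha <- p$admixture_fraction
        from_a <- stats::runif(k) < alpha
        out <- matrix(0L, L, k)
        if (any(from_a))
          out[, from_a] <- pool_gametes(HA, posM, Lm, sum(from_a))
        if (any(!from_a))
          out[, !from_a] <- pool_gametes(HB, posM, Lm, sum(!from_a))
        state[[nm]] <- out
        traj[[paste0("anc_", nm)]] <- data.frame(
          population = nm, parent_a = p$parents[1],
          founder_fraction_a = mean(from_a))
      }
    }
    # evolution of standing populations
    for (nm in names(state)) {
      if (birth[[nm]] == t && birth[[nm]] < horizon) next  # just founded
      if (t_next < last_need[[nm]]) next
      state[[nm]] <- reproduce(nm, t_next, state[[nm]])
    }
    # record sweep trajectories; drop exhausted ancestors
    for (sw in sweeps) {
      if (t_next >= sw$start_generation) next
      for (nm in intersect(sw$target_populations, names(state))) {
        traj[[length(traj) + 1L]] <- data.frame(
          chrom = chrom_name, population = nm, pos_bp = pos[sw$focal],
          generation = t_next, freq = mean(state[[nm]][sw$focal, ]))
      }
    }
    for (nm in names(state)) {
      if (last_need[[nm]] > t_next) state[[nm]] <- NULL
    }
  }

  for (sw in sweeps) {
    for (nm in sw$target_populations) {
      pf <- if (nm %in% names(state)) mean(state[[nm]][sw$focal, ]) else NA
      sweep_log[[length(sweep_log) + 1L]] <- data.frame(
        chrom = chrom_name, population = nm, pos_bp = pos[sw$focal],
        s = sw$s, start_generation = sw$start_generation,
        final_freq = pf, established = !is.na(pf) && pf > 0.5,
        lost = !is.na(pf) && pf == 0)
    }
  }

  variants <- data.frame(
    id = sprintf("snp%s_%d", chrom_name, seq_len(L)),
    chrom = chrom_name, pos_bp = pos,
    allele_ref = "A", allele_alt = "B", stringsAsFactors = FALSE)

  list(variants = variants, state = state, p0 = p0,
       founder_freq = founder_freq,
       traj = traj, sweep_log = sweep_log, n_redraws = n_redraws)
}

#' Run the forward Wright-Fisher simulation
#'
#' Forward-in-time diploid Wright-Fisher simulation with recombination
#' over standing variation (no new mutation: all variation is standing,
#' as on a fixed SNP-array panel). Root populations start at the horizon
#' with allele frequencies drawn uniformly from `init_freq_range` and
#' haplotypes at linkage equilibrium; each generation every offspring
#' draws two parents (fitness-weighted under a sweep) and each gamete
#' recombines with a Poisson number of crossovers at uniform map
#' positions. Splits found a child population by reproduction from the
#' parent pool; two-parent populations mix gametes from both parents.
#' At present, the named populations are sampled without replacement.
#'
#' @param config a [sim_config()].
#' @return a list with elements
#'   \describe{
#'     \item{genotypes}{a [genotype_dataset()] over all sampled
#'       populations (no missing calls),}
#'     \item{haplotypes}{named list of per-population
#'       [haplotype_set()]s (all chromosomes concatenated),}
#'     \item{truth}{list with `init_freqs`, `sweeps`, `ancestry`,
#'       `trajectories`, and `n_redraws` describing the realized
#'       simulation.}
#'   }
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  chrom_names <- as.character(seq_len(config$n_chrom))
  runs <- lapply(chrom_names, function(ch) simulate_chrom(config, ch))

  sampled <- names(config$sample_sizes)
  hapsets <- list()
  all_calls <- list()
  for (nm in sampled) {
    n_s <- config$sample_sizes[[nm]]
    hap_blocks <- list()
    for (r in runs) {
      pool <- r$state[[nm]]
      n_pool <- ncol(pool) %/% 2L
      pick <- sort(sample.int(n_pool, n_s))
      cols <- as.vector(rbind(2L * pick - 1L, 2L * pick))
      hap_blocks[[length(hap_blocks) + 1L]] <- pool[, cols, drop = FALSE]
    }
    haps <- t(do.call(rbind, hap_blocks))   # haplotypes x all variants
    variants <- do.call(rbind, lapply(runs, `[[`, "variants"))
    ids <- sprintf("%s_%d", nm, seq_len(n_s))
    hapsets[[nm]] <- haplotype_set(haps, variants, samples = ids)
    odd <- seq(1L, 2L * n_s, by = 2L)
    all_calls[[nm]] <- haps[odd, , drop = FALSE] +
      haps[odd + 1L, , drop = FALSE]
  }
  variants <- do.call(rbind, lapply(runs, `[[`, "variants"))
  calls <- do.call(rbind, all_calls)
  samples <- unlist(lapply(hapsets, `[[`, "samples"), use.names = FALSE)
  pops <- stats::setNames(
    rep(sampled, times = vapply(sampled, function(nm)
      as.integer(config$sample_sizes[[nm]]), 0L)),
    samples)
  ds <- genotype_dataset(calls, variants, samples, pops)

  trajs <- do.call(rbind, unlist(lapply(runs, function(r)
    Filter(function(x) "generation" %in% names(x), r$traj)),
    recursive = FALSE))
  anc <- do.call(rbind, unlist(lapply(runs, function(r)
    Filter(function(x) "founder_fraction_a" %in% names(x), r$traj)),
    recursive = FALSE))
  truth <- list(
    init_freqs = do.call(rbind, lapply(seq_along(runs), function(i) {
      df <- data.frame(chrom = chrom_names[i], id = runs[[i]]$variants$id,
                       p0 = runs[[i]]$p0, stringsAsFactors = FALSE)
      for (nm in names(runs[[i]]$founder_freq))
        df[[paste0("founder_", nm)]] <- runs[[i]]$founder_freq[[nm]]
      df
    })),
    sweeps = do.call(rbind, unlist(lapply(runs, `[[`, "sweep_log"),
                                   recursive = FALSE)),
    ancestry = anc,
    trajectories = trajs,
    n_redraws = sum(vapply(runs, `[[`, 0L, "n_redraws")))

  list(genotypes = ds, haplotypes = hapsets, truth = truth)
}

#' Default scaled-down cattle demography
#'
#' A compact emulation of the structure of world cattle diversity: an
#' ancestral pool splitting into a taurine-like and an indicine-like
#' lineage, each splitting again into an African and a non-African
#' population, plus a two-parent hybrid; every terminal population
#' declines toward the present. Simulation depth and sizes are rescaled
#' (about 1 simulated generation per 4 real generations) so a forward
#' run stays tractable; a hard sweep confined to the taurine lineage is
#' included by default.
#'
#' @param seed RNG seed.
#' @param n_variants SNPs per chromosome, default 2000.
#' @param n_chrom chromosomes, default 1.
#' @param sample_size diploids sampled per population, default 25.
#' @param with_sweep include the taurine-lineage sweep, default `TRUE`.
#' @return a [sim_config()].
#' @export
default_cattle_config <- function(seed = 1L, n_variants = 2000,
                                  n_chrom = 1L, sample_size = 25,
                                  with_sweep = TRUE) {
  decline <- function(from) cbind(generation = c(200, 0), ne = c(from, 60))
  pops <- list(
    population_spec("ancestor", 250),
    population_spec("taurine", 250, parents = "ancestor",
                    split_generation = 450),
    population_spec("indicine", 250, parents = "ancestor",
                    split_generation = 450),
    population_spec("eu_taurine", decline(250), parents = "taurine",
                    split_generation = 200),
    population_spec("af_taurine", decline(250), parents = "taurine",
                    split_generation = 200),
    population_spec("as_indicine", decline(250), parents = "indicine",
                    split_generation = 200),
    population_spec("af_indicine", decline(250), parents = "indicine",
                    split_generation = 200),
    population_spec("hybrid", 100, parents = c("eu_taurine", "as_indicine"),
                    admixture_fraction = 0.6, split_generation = 10))
  sweeps <- if (with_sweep)
    list(sweep_spec(pos_bp = 25e6, s = 0.2, start_generation = 60,
                    target_populations = c("eu_taurine", "af_taurine")))
  else list()
  sizes <- stats::setNames(rep(sample_size, 5),
                           c("eu_taurine", "af_taurine", "as_indicine",
                             "af_indicine", "hybrid"))
  sim_config(populations = pops, sample_sizes = sizes,
             chrom_length_bp = 5e7, n_variants = n_variants,
             n_chrom = n_chrom, sweeps = sweeps, seed = seed,
             horizon_generations = 500L,
             resample_until_established = TRUE)
}
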
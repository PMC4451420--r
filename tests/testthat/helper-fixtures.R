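# small in-code fixtures shared across test files

make_variants <- function(pos, chrom = "1", ids = NULL) {
  data.frame(id = ids %||% paste0("snp", seq_along(pos)),
             chrom = chrom, pos_bp = as.integer(pos),
             allele_ref = "A", allele_alt = "B",
             stringsAsFactors = FALSE)
}

make_ds <- function(calls, pos = NULL, pops = NULL, chrom = "1") {
  calls <- as.matrix(calls)
  n <- nrow(calls)
  if (is.null(pos)) pos <- seq_len(ncol(calls)) * 1000L
  samples <- paste0("ind", seq_len(n))
  if (is.null(pops)) pops <- rep("pop1", n)
  genotype_dataset(calls, make_variants(pos, chrom), samples,
                   stats::setNames(pops, samples))
}

make_haps <- function(haps, pos = NULL, chrom = "1") {
  haps <- as.matrix(haps)
  if (is.null(pos)) pos <- seq_len(ncol(haps)) * 1000L
  haplotype_set(haps, make_variants(pos, chrom))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

write_ped_fixture <- function(dir, ped_lines, map_lines, pop_lines) {
  ped <- file.path(dir, "toy.ped")
  map <- file.path(dir, "toy.map")
  pop <- file.path(dir, "toy.pop")
  writeLines(ped_lines, ped)
  writeLines(map_lines, map)
  writeLines(pop_lines, pop)
  list(ped = ped, map = map, pop = pop)
}

# brute-force whole-sample EHH: fraction of haplotype pairs identical
# over the inclusive index range core..x, by direct pairwise comparison
# of the allele strings
brute_ehh <- function(h, core, x) {
  rng <- min(core, x):max(core, x)
  s <- apply(h[, rng, drop = FALSE], 1, paste, collapse = "")
  n <- length(s)
  (sum(outer(s, s, "==")) - n) / 2 / choose(n, 2)
}

# tiny two-population scenario used by several suites
two_pop_sim <- function(seed = 7, n_variants = 500, split = 100,
                        horizon = 200, ne = 100, n_sample = 20,
                        chrom_length = 2e7, n_chrom = 1) {
  cfg <- sim_config(
    populations = list(
      population_spec("anc", ne),
      population_spec("A", ne, parents = "anc", split_generation = split),
      population_spec("B", ne, parents = "anc", split_generation = split)),
    sample_sizes = c(A = n_sample, B = n_sample),
    chrom_length_bp = chrom_length, n_variants = n_variants,
    n_chrom = n_chrom, seed = seed, horizon_generations = horizon)
  simulate_genotypes(cfg)
}
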
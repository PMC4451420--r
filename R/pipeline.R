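#' Replicated pairwise comparison design
#'
#' Builds the three comparison families of the replicated selection
#' scan: a between-species family pairing each taurine with an indicine
#' population (threshold `m = K - 1`, so a SNP untested in one pairing
#' can still be called), and two within-species families pairing
#' populations across continents (threshold `m = K`, unanimity).
#'
#' @param taurine,indicine equal-length character vectors of population
#'   names paired position-by-position for the between-species family
#'   (the published design uses 4 + 4).
#' @param taurine_groups,indicine_groups optional lists of two
#'   equal-length vectors (e.g. European and African taurine) paired
#'   position-by-position for the within-species families (the
#'   published design uses 3 + 3).
#' @return list of comparison designs, each with `name`, `pairs`
#'   (data frame `pop_a`, `pop_b`) and `m`.
#' @export
build_figure1_design <- function(taurine, indicine,
                                 taurine_groups = NULL,
                                 indicine_groups = NULL) {
  if (!length(taurine) || !length(indicine))
    stop("empty population group")
  if (length(taurine) != length(indicine))
    stop("between-species groups must have equal sizes (got ",
         length(taurine), " and ", length(indicine), ")")
  dup <- intersect(taurine, indicine)
  if (length(dup))
    stop("population(s) in both groups: ", paste(dup, collapse = ", "))
  k <- length(taurine)
  designs <- list(list(
    name = "between_species",
    pairs = data.frame(pop_a = taurine, pop_b = indicine,
                       stringsAsFactors = FALSE),
    m = max(1L, k - 1L)))
  within <- function(groups, label) {
    if (is.null(groups)) return(NULL)
    a <- groups[[1]]
    b <- groups[[2]]
    if (length(a) != length(b))
      stop("within-", label, " groups must have equal sizes")
    if (length(intersect(a, b)))
      stop("population(s) in both within-", label, " groups: ",
           paste(intersect(a, b), collapse = ", "))
    list(name = paste0("within_", label),
         pairs = data.frame(pop_a = a, pop_b = b, stringsAsFactors = FALSE),
         m = length(a))
  }
  wt <- within(taurine_groups, "taurine")
  wi <- within(indicine_groups, "indicine")
  if (!is.null(wt)) designs[[length(designs) + 1L]] <- wt
  if (!is.null(wi)) designs[[length(designs) + 1L]] <- wi
  designs
}

pipeline_defaults <- function() {
  list(sample_min = 0.95, snp_min = 0.95, maf_min = 0.05,
       q_low = 0.05, q_high = 0.95, max_gap_bp = 400000,
       ehh_cutoff = 0.05, n_bins = 30, min_bp = 5000, max_bp = 1e6,
       window_bp = 50000, bootstrap_replicates = 100,
       morgans_per_bp = 1e-8)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full analysis pipeline
#'
#' Executes, in order: simulation (or file input), call-rate QC,
#' per-population diversity, Reynolds/NJ tree with bootstrap, per-
#' population Ne trajectories, the XP-EHH comparisons of the design,
#' consensus calling, and optional gene annotation. All stage outputs
#' are written as TSV/Newick under `out_dir`, together with a JSON
#' manifest recording parameters, the seed, per-stage record counts and
#' output checksums; identical config and seed reproduce identical
#' outputs.
#'
#' @param config a list (or path to a YAML file) with elements:
#'   \describe{
#'     \item{sim}{a [sim_config()] for synthetic mode, or}
#'     \item{ped, map, pop_table, haplotypes}{input paths for real
#'       data (`haplotypes` a named list of per-population HAPS
#'       files),}
#'     \item{design}{a design from [build_figure1_design()], or a list
#'       with the arguments to build one,}
#'     \item{features, features_fmt}{optional gene-feature file for
#'       annotation,}
#'     \item{thresholds}{overrides of the documented defaults,}
#'     \item{seed}{integer seed,}
#'     \item{out_dir}{output directory.}
#'   }
#' @return the manifest, invisibly; written as `manifest.json`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  stopifnot(is.list(config), !is.null(config$out_dir))
  thr <- utils::modifyList(pipeline_defaults(),
                           as.list(config$thresholds %||% list()))
  seed <- as.integer(config$seed %||% 1L)
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(package = "bovidemog",
                   version = as.character(utils::packageVersion("bovidemog")),
                   seed = seed, thresholds = thr, stages = list())
  outputs <- character()
  fail <- function(stage, err) {
    manifest$error <- list(stage = stage, message = conditionMessage(err))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    stop("pipeline failed at stage '", stage, "': ",
         conditionMessage(err), call. = FALSE)
  }
  stage <- function(name, expr) {
    res <- tryCatch(force(expr), error = function(e) fail(name, e))
    res
  }

  # ---- input ----
  inputs <- stage("input", {
    if (!is.null(config$sim)) {
      if (!inherits(config$sim, "sim_config"))
        config$sim <- sim_config_from_list(config$sim)
      sim <- simulate_genotypes(config$sim)
      write_tsv(sim$truth$sweeps %||%
                  data.frame(note = "no sweeps simulated"),
                file.path(out_dir, "truth_sweeps.tsv"))
      sim
    } else {
      ds <- read_genotypes(config$ped, config$map, config$pop_table)
      haps <- lapply(config$haplotypes, read_haplotypes)
      list(genotypes = ds, haplotypes = haps, truth = NULL)
    }
  })
  ds <- inputs$genotypes
  manifest$stages$input <- list(samples = length(ds$samples),
                                variants = nrow(ds$variants))

  # ---- design validation ----
  design <- stage("design", {
    d <- config$design
    if (is.null(d)) NULL
    else {
      if (!is.null(d$taurine))
        d <- do.call(build_figure1_design, d)
      pops_used <- unique(unlist(lapply(d, function(x)
        c(x$pairs$pop_a, x$pairs$pop_b))))
      unknown <- setdiff(pops_used, unique(unname(ds$populations)))
      if (length(unknown))
        stop("design names unknown population(s): ",
             paste(unknown, collapse = ", "))
      d
    }
  })

  set.seed(seed)

  # ---- qc ----
  ds <- stage("qc", filter_call_rate(ds, thr$sample_min, thr$snp_min))
  manifest$stages$qc <- list(samples_kept = length(ds$samples),
                             variants_kept = nrow(ds$variants))

  # ---- diversity ----
  div <- stage("diversity", diversity_table(ds))
  outputs <- c(outputs, write_tsv(div, file.path(out_dir, "diversity.tsv")))
  manifest$stages$diversity <- list(populations = nrow(div))

  # ---- tree ----
  stage("tree", {
    dmat <- reynolds_matrix(ds)
    write_dist_phylip(dmat, file.path(out_dir, "reynolds.dist"))
    tr <- bootstrap_support(ds, replicates = thr$bootstrap_replicates,
                            seed = seed)
    ape::write.tree(tr, file.path(out_dir, "nj_bootstrap.nwk"))
    outputs <- c(outputs, file.path(out_dir, "reynolds.dist"),
                  file.path(out_dir, "nj_bootstrap.nwk"))
    manifest$stages$tree <- list(populations = nrow(dmat),
                                  replicates = thr$bootstrap_replicates)
  })

  # ---- ne trajectories ----
  if (!is.null(inputs$haplotypes)) stage("ne", {
    rows <- list()
    for (nm in names(inputs$haplotypes)) {
      tj <- tryCatch(
        ne_trajectory(inputs$haplotypes[[nm]], population = nm,
                      n_bins = thr$n_bins, min_bp = thr$min_bp,
                      max_bp = thr$max_bp, maf_min = thr$maf_min,
                      morgans_per_bp = thr$morgans_per_bp),
        error = function(e) NULL)
      if (is.null(tj)) next
      b <- tj$bins
      b$population <- nm
      b$harmonic_mean_ne <- tj$harmonic_mean_ne
      rows[[nm]] <- b
    }
    ne_out <- do.call(rbind, rows)
    outputs <- c(outputs,
                  write_tsv(ne_out, file.path(out_dir, "ne_trajectory.tsv")))
    manifest$stages$ne <- list(populations = length(rows))
  })

  # ---- selection scan + consensus ----
  if (!is.null(design) && !is.null(inputs$haplotypes)) stage("xpehh", {
    calls_all <- list()
    for (d in design) {
      recs <- list()
      for (i in seq_len(nrow(d$pairs))) {
        a <- d$pairs$pop_a[i]
        b <- d$pairs$pop_b[i]
        rec <- xpehh(inputs$haplotypes[[a]], inputs$haplotypes[[b]],
                     maf_min = thr$maf_min, max_gap_bp = thr$max_gap_bp,
                     cutoff = thr$ehh_cutoff)
        rec <- flag_outliers(standardize_by_chrom(rec),
                             q_low = thr$q_low, q_high = thr$q_high)
        nm <- paste0(a, "_vs_", b)
        outputs <- c(outputs, write_tsv(
          rec, file.path(out_dir, paste0("xpehh_", d$name, "_", nm, ".tsv"))))
        recs[[nm]] <- rec
      }
      cs <- comparison_set(d$name, recs, m = d$m)
      calls <- consensus(cs)
      outputs <- c(outputs, write_tsv(
        calls, file.path(out_dir, paste0("consensus_", d$name, ".tsv"))))
      calls_all[[d$name]] <- calls
      manifest$stages$xpehh[[d$name]] <-
        list(comparisons = nrow(d$pairs), m = d$m,
             snps_called = nrow(calls))
    }

    # ---- annotation ----
    if (!is.null(config$features)) {
      feats <- read_features(config$features,
                             fmt = config$features_fmt %||% "gff3")
      for (nm in names(calls_all)) {
        links <- link_genes(calls_all[[nm]], feats,
                            window_bp = thr$window_bp)
        tal <- tally_biotypes(links)
        outputs <- c(outputs,
                      write_tsv(links, file.path(out_dir,
                                                 paste0("genes_", nm, ".tsv"))),
                      write_tsv(tal, file.path(out_dir,
                                               paste0("biotypes_", nm, ".tsv"))))
        manifest$stages$annotate[[nm]] <- list(links = nrow(links))
      }
    }
  })

  manifest$outputs <- as.list(tools::md5sum(sort(unique(outputs))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# rebuild a sim_config from the plain-list form a YAML config yields
sim_config_from_list <- function(x) {
  pops <- lapply(x$populations, function(p) {
    ne <- p$ne
    if (is.list(ne) || (!is.null(dim(ne)) || length(ne) > 1)) {
      ne <- do.call(rbind, lapply(ne, function(row)
        c(generation = row$generation %||% row[[1]],
          ne = row$ne %||% row[[2]])))
    }
    population_spec(p$name, ne,
                    parents = unlist(p$parents) %||% character(),
                    admixture_fraction = p$admixture_fraction,
                    split_generation = p$split_generation)
  })
  sweeps <- lapply(x$sweeps %||% list(), function(sw)
    sweep_spec(pos_bp = sw$pos_bp, s = sw$s,
               start_generation = sw$start_generation,
               target_populations = unlist(sw$target_populations),
               chrom = sw$chrom %||% "1",
               initial_freq = sw$initial_freq))
  do.call(sim_config, c(
    list(populations = pops, sample_sizes = unlist(x$sample_sizes),
         sweeps = sweeps),
    x[intersect(names(x),
                c("chrom_length_bp", "n_variants", "recomb_rate",
                  "n_chrom", "seed", "horizon_generations",
                  "init_freq_range", "resample_until_established"))]))
}
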
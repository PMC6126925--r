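#' Parse a flat-text configuration file
#'
#' Reads a `key = value` file (one pair per line, `#` comments allowed)
#' into a validated [sim_config()].  `lambda = inf` selects the
#' no-lifespan mode.  Unknown keys and out-of-range values are errors.
#'
#' @param path configuration file.
#' @return A [sim_config()].
#' @export
parse_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  keys <- character(0)
  vals <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2) stop("malformed configuration line: ", ln)
    keys <- c(keys, trimws(kv[1]))
    vals <- c(vals, trimws(kv[2]))
  }
  known <- names(formals(sim_config))
  unknown <- setdiff(keys, known)
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  args <- list()
  for (i in seq_along(keys)) {
    v <- vals[[i]]
    args[[keys[i]]] <-
      if (keys[i] == "mode") v
      else if (tolower(v) %in% c("inf", "infinity")) Inf
      else as.numeric(v)
  }
  do.call(sim_config, args)
}

#' Write a resolved configuration
#'
#' @param cfg a [sim_config()].
#' @param path output file (`key = value` lines, re-readable by
#'   [parse_config()]).
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "sim_config"))
  writeLines(sprintf("%s = %s", names(cfg),
                     vapply(cfg, function(v) format(v, digits = 15),
                            character(1))), path)
  invisible(path)
}

#' Write the standard output files of a run
#'
#' Emits the delimited-text outputs of a simulation into a directory:
#' `summary.tsv` (per-generation totals), `abundance.tsv` (long format:
#' generation, strain, count, from the snapshots), one
#' `matrix_<generation>.tsv` per snapshot, `lineage.tsv`,
#' `phylogeny.nwk` and `config_resolved.txt`.
#'
#' @param sim an `iteem_sim`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_run <- function(sim, dir) {
  stopifnot(inherits(sim, "iteem_sim"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(sim$summary, file.path(dir, "summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  ab <- do.call(rbind, lapply(sim$snapshots, function(sn)
    data.frame(generation = sn$generation,
               strain = as.integer(sn$handles),
               count = as.numeric(sn$abundance))))
  utils::write.table(ab, file.path(dir, "abundance.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  for (sn in sim$snapshots) {
    im <- interaction_matrix(`dimnames<-`(
      sn$matrix, rep(list(as.character(sn$handles)), 2)))
    write_matrix_snapshot(im, file.path(dir,
                                        sprintf("matrix_%d.tsv",
                                                sn$generation)))
  }
  write_lineage(sim, file.path(dir, "lineage.tsv"))
  writeLines(to_newick(sim$lineage,
                       t_end = sim$final$generation),
             file.path(dir, "phylogeny.nwk"))
  write_config(sim$config, file.path(dir, "config_resolved.txt"))
  invisible(dir)
}

#' Sweep over trade-off and lifespan
#'
#' Runs the simulation over a grid of trade-off parameters `deltas` and
#' lifespans `lambdas` (plus, optionally, neutral-model cells as a
#' baseline), with several independent seeds per cell, and summarises each
#' run by its late-time consensus diversity and dominance-network
#' structure.  The consensus normalisation ensemble is the set of *all*
#' late-time snapshots of the whole sweep, so consensus values are
#' comparable across cells (and only within one sweep).
#'
#' Per run, snapshots from the last `last_fraction` of the trajectory are
#' scored with [diversity_report()]; a run that went extinct before that
#' window contributes a consensus of 0 (an empty community has no
#' diversity).  Per-run seeds are `seeds` for the first cell and
#' deterministic distinct offsets of them for later cells, so a
#' single-cell sweep reproduces plain [run_simulation()] calls exactly.
#'
#' @param deltas trade-off values for the trait-driven cells.
#' @param lambdas lifespans (recycled over the grid with `deltas`;
#'   the grid is their cross product).
#' @param seeds integer seeds; one run per seed per cell.
#' @param neutral_cells how many neutral-baseline cells to add (0 or 1).
#' @param ns,mu,m,generations,record_every,r_neutral,initial_occupancy
#'   shared simulation parameters, as in [sim_config()].
#' @param last_fraction fraction of the trajectory (from the end) used for
#'   the late-time averages.
#' @param n_random randomised-ensemble size for cycle normalisation
#'   (0 disables network statistics).
#' @return An `iteem_sweep` list: `runs` (one row per run: cell labels,
#'   seed, consensus, mean dominance weight, normalised mean cycle
#'   strength, extinct flag), `cells` (per-cell mean/sd/median consensus),
#'   `reports` (the stacked snapshot reports with consensus), and the
#'   shared parameters.
#' @export
run_sweep <- function(deltas, lambdas = Inf, seeds = 1:3, neutral_cells = 1,
                      ns = 1000, mu = 1e-3, m = 0.02, generations = 10000,
                      record_every = 1000, r_neutral = 0.5,
                      initial_occupancy = 0.1, last_fraction = 0.5,
                      n_random = 100) {
  grid <- expand.grid(delta = deltas, lambda = lambdas,
                      KEEP.OUT.ATTRS = FALSE)
  grid$mode <- "iteem"
  if (neutral_cells > 0)
    grid <- rbind(grid, data.frame(delta = NA_real_, lambda = Inf,
                                   mode = "neutral"))
  runs <- list()
  reports <- list()
  seed_span <- max(seeds) + 1
  for (ci in seq_len(nrow(grid))) {
    for (sj in seq_along(seeds)) {
      seed <- seeds[sj] + (ci - 1L) * seed_span
      cfg <- sim_config(
        ns = ns, delta = if (grid$mode[ci] == "neutral") 0 else
          grid$delta[ci],
        lambda = grid$lambda[ci], mu = mu, m = m,
        generations = generations, seed = seed,
        record_every = record_every, mode = grid$mode[ci],
        r_neutral = r_neutral, initial_occupancy = initial_occupancy)
      sim <- run_simulation(cfg)
      gens <- sim$snapshot_generations
      late <- which(gens > (1 - last_fraction) * generations)
      run_row <- data.frame(
        delta = grid$delta[ci], lambda = grid$lambda[ci],
        mode = grid$mode[ci], seed = seed, extinct = sim$extinct,
        n_late_snapshots = length(late),
        mean_W = NA_real_, n_cycles = NA_real_,
        normalized_strength = NA_real_, consensus = NA_real_)
      if (length(late) > 0) {
        reps <- do.call(rbind, lapply(sim$snapshots[late],
                                      diversity_report))
        reps$cell <- ci
        reps$seed <- seed
        reports[[length(reports) + 1]] <- reps
        if (n_random > 0) {
          ns_stats <- do.call(rbind, lapply(
            sim$snapshots[late],
            function(sn) network_stats(sn$matrix, n_random = n_random)))
          run_row$mean_W <- mean(ns_stats$mean_W)
          run_row$n_cycles <- mean(ns_stats$n_cycles)
          run_row$normalized_strength <-
            mean(ns_stats$normalized_strength, na.rm = TRUE)
        }
      }
      runs[[length(runs) + 1]] <- run_row
    }
  }
  runs <- do.call(rbind, runs)
  if (length(reports) > 0) {
    reports <- do.call(rbind, reports)
    reports$consensus <- consensus_diversity(reports)
    agg <- tapply(reports$consensus,
                  interaction(reports$cell, reports$seed, drop = TRUE),
                  mean)
    key <- strsplit(names(agg), ".", fixed = TRUE)
    for (i in seq_along(agg)) {
      sd_ <- as.integer(key[[i]][2])  # per-run seeds are globally unique
      runs$consensus[runs$seed == sd_] <- agg[i]
    }
  } else reports <- NULL
  runs$consensus[is.na(runs$consensus) & runs$extinct] <- 0
  cell_key <- interaction(ifelse(is.na(runs$delta), "neutral", runs$delta),
                          runs$lambda, runs$mode, drop = TRUE)
  cells <- do.call(rbind, lapply(split(runs, cell_key), function(g)
    data.frame(delta = g$delta[1], lambda = g$lambda[1], mode = g$mode[1],
               n_runs = nrow(g),
               consensus_mean = mean(g$consensus, na.rm = TRUE),
               consensus_sd = stats::sd(g$consensus),
               consensus_median = stats::median(g$consensus, na.rm = TRUE),
               mean_W = mean(g$mean_W),
               normalized_strength = mean(g$normalized_strength))))
  rownames(cells) <- NULL
  structure(list(runs = runs, cells = cells, reports = reports,
                 parameters = list(ns = ns, mu = mu, m = m,
                                   generations = generations,
                                   record_every = record_every,
                                   last_fraction = last_fraction,
                                   seeds = seeds)),
            class = "iteem_sweep")
}

#' @export
print.iteem_sweep <- function(x, ...) {
  cat("Trade-off / lifespan sweep:",
      nrow(x$cells), "cell(s),", nrow(x$runs), "run(s)\n")
  print(x$cells, digits = 3)
  invisible(x)
}

#' Write the phase-diagram table of a sweep
#'
#' @param sweep an `iteem_sweep`.
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
write_phase_diagram <- function(sweep, path) {
  stopifnot(inherits(sweep, "iteem_sweep"))
  utils::write.table(sweep$cells, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
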
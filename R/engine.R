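#' Simulation configuration
#'
#' Assembles and validates the parameters of an individual-based run.
#'
#' @param ns number of resource sites \eqn{N_s} (each supports one
#'   individual).
#' @param delta trade-off shape parameter \eqn{\delta \in [0,1)}; see
#'   [replication_probability()].
#' @param lambda mean lifespan \eqn{\lambda} in generations.  Individual
#'   lifespans are drawn at birth from a Poisson distribution with this
#'   mean; `Inf` disables the death step entirely, so individuals die only
#'   by losing a competitive encounter.
#' @param mu mutation probability \eqn{\mu} per replication.
#' @param m mutation width: standard deviation of the Gaussian perturbation
#'   applied independently to every entry of the parental interaction trait.
#' @param generations number of generations to simulate; each generation is
#'   `ns` sequential replication trials followed by one death step.
#' @param seed integer seed; the run is fully reproducible given the seed
#'   (a single RNG stream with a fixed per-trial draw order).
#' @param record_every snapshot interval in generations (abundances and the
#'   full interaction matrix are stored at these times, plus generation 0).
#' @param mode `"iteem"` (trait-driven replication and contests) or
#'   `"neutral"`: traits still mutate and drift, but every contest is decided
#'   at probability 0.5 and all strains share the fixed replication
#'   probability `r_neutral`, giving a pure ecological-drift baseline.
#' @param r_neutral common replication probability in neutral mode.
#' @param initial_occupancy fraction of sites seeded with founder
#'   individuals at generation 0.
#' @return A `sim_config` list.
#' @export
sim_config <- function(ns = 1000, delta = 0.5, lambda = Inf, mu = 1e-3,
                       m = 0.02, generations = 1000, seed = 1,
                       record_every = 1000, mode = c("iteem", "neutral"),
                       r_neutral = 0.5, initial_occupancy = 0.1) {
  mode <- match.arg(mode)
  bad <- function(msg) stop("invalid configuration: ", msg, call. = FALSE)
  if (length(ns) != 1 || is.na(ns) || ns < 1 || ns != round(ns))
    bad("ns must be a positive integer")
  if (length(delta) != 1 || !is.finite(delta) || delta < 0 || delta >= 1)
    bad("delta must lie in [0, 1)")
  if (length(lambda) != 1 || is.na(lambda) || lambda <= 0)
    bad("lambda must be positive (Inf allowed)")
  if (length(mu) != 1 || !is.finite(mu) || mu < 0 || mu > 1)
    bad("mu must lie in [0, 1]")
  if (length(m) != 1 || !is.finite(m) || m <= 0)
    bad("m must be positive")
  if (length(generations) != 1 || !is.finite(generations) || generations < 1)
    bad("generations must be >= 1")
  if (length(record_every) != 1 || !is.finite(record_every) ||
      record_every < 1)
    bad("record_every must be >= 1")
  if (length(initial_occupancy) != 1 || !is.finite(initial_occupancy) ||
      initial_occupancy <= 0 || initial_occupancy > 1)
    bad("initial_occupancy must lie in (0, 1]")
  if (length(r_neutral) != 1 || !is.finite(r_neutral) ||
      r_neutral < 0 || r_neutral > 1)
    bad("r_neutral must lie in [0, 1]")
  structure(list(
    ns = as.integer(ns), delta = delta, lambda = lambda, mu = mu, m = m,
    generations = as.integer(generations), seed = as.integer(seed),
    record_every = as.integer(record_every), mode = mode,
    r_neutral = r_neutral, initial_occupancy = initial_occupancy),
    class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Simulation configuration\n")
  for (k in names(x)) cat(sprintf("  %-18s %s\n", k, format(x[[k]])))
  invisible(x)
}

.new_engine <- function(cfg) {
  .eng_new(cfg$ns, cfg$delta, cfg$lambda, cfg$mu, cfg$m,
           cfg$mode == "neutral", cfg$r_neutral, cfg$initial_occupancy)
}

#' Run an eco-evolutionary simulation
#'
#' Simulates the individual-based dynamics: every generation consists of
#' `ns` sequential replication trials — a uniformly chosen individual of
#' strain \eqn{\alpha} replicates with probability \eqn{r_\alpha}; the
#' offspring mutates with probability \eqn{\mu} (perturbing the inherited
#' interaction trait); it is assigned to a uniformly chosen site, occupying
#' it if empty or fighting the current holder, whom it kills with
#' probability \eqn{I_{\text{offspring},\,\text{holder}}}; newborns draw a
#' Poisson(\eqn{\lambda}) lifespan — followed by a single death step that
#' removes all individuals that have reached their lifespan.  Competitive
#' ability and replication probability are recomputed for all live strains
#' whenever the strain roster changes; strains at zero abundance are removed
#' immediately.
#'
#' The run starts from a single founder strain occupying
#' `round(initial_occupancy * ns)` sites and ends after `generations`
#' generations or upon global extinction (which is reported, not an error).
#'
#' @param cfg a [sim_config()]; alternatively pass the same arguments via
#'   `...` to be forwarded to [sim_config()].
#' @param init optional custom initial community for controlled experiments:
#'   a list with `matrix` (reciprocal interaction matrix), `abundance`
#'   (integer per strain) and optionally `r` (fixed per-strain replication
#'   probabilities overriding the trade-off).  When supplied the founder
#'   seeding and `initial_occupancy` are ignored.
#' @param ... arguments forwarded to [sim_config()] when `cfg` is missing.
#' @return An object of class `iteem_sim`: a list with the resolved
#'   `config`, a per-generation `summary` data frame (individuals, strains,
#'   births, contest deaths, lifespan deaths, established mutations),
#'   `snapshots` (list of generation/handles/abundance/matrix),
#'   `lineage` (strain genealogy data frame: id, parent, t_birth,
#'   t_extinct), `final` state and the `extinct` flag.
#' @seealso [summary.iteem_sim()], [plot.iteem_sim()], [diversity_report()],
#'   [build_dominance()], [lineage_tree()]
#' @export
run_simulation <- function(cfg = NULL, init = NULL, ...) {
  if (is.null(cfg)) cfg <- sim_config(...)
  if (!inherits(cfg, "sim_config")) stop("cfg must be a sim_config object")
  set.seed(cfg$seed)
  ptr <- .new_engine(cfg)
  if (is.null(init)) {
    .eng_init_founder(ptr)
  } else {
    im <- init$matrix
    if (inherits(im, "interaction_matrix")) im <- im$entries
    .eng_init_custom(ptr, im, as.integer(init$abundance),
                     if (is.null(init$r)) NULL else as.numeric(init$r))
  }
  res <- .eng_run(ptr, cfg$generations, cfg$record_every, TRUE)
  lin <- as.data.frame(.eng_lineage(ptr))
  structure(list(
    config = cfg,
    summary = res$summary,
    snapshots = res$snapshots,
    snapshot_generations = res$snapshot_generations,
    lineage = lin,
    final = .eng_state(ptr),
    extinct = res$extinct),
    class = "iteem_sim")
}

#' @export
print.iteem_sim <- function(x, ...) {
  cfg <- x$config
  cat("Individual-based eco-evolutionary simulation\n")
  cat(sprintf("  sites %d | delta %.3g | lambda %s | mu %.3g | m %.3g | mode %s\n",
              cfg$ns, cfg$delta, format(cfg$lambda), cfg$mu, cfg$m, cfg$mode))
  n <- nrow(x$summary)
  if (x$extinct) {
    cat(sprintf("  community went extinct after %d generation(s)\n",
                x$final$generation))
  } else if (n > 0) {
    last <- x$summary[n, ]
    cat(sprintf("  generation %d: %d individuals in %d strain(s)\n",
                as.integer(last$generation), as.integer(last$n_individuals),
                as.integer(last$n_strains)))
  }
  cat(sprintf("  %d snapshot(s), %d strain(s) ever recorded\n",
              length(x$snapshots), nrow(x$lineage)))
  invisible(x)
}

#' Summarise a simulation
#'
#' @param object an `iteem_sim` object.
#' @param last_fraction fraction of the trajectory (counting from the end)
#'   over which the late-time averages are taken.
#' @param ... unused.
#' @return A list with the late-time mean occupancy, strain richness and
#'   event rates, plus the full per-generation summary.
#' @export
summary.iteem_sim <- function(object, last_fraction = 0.5, ...) {
  s <- object$summary
  n <- nrow(s)
  keep <- if (n > 0) s[s$generation > (1 - last_fraction) *
                         max(s$generation), , drop = FALSE] else s
  out <- list(
    config = object$config,
    extinct = object$extinct,
    generations_run = if (n) max(s$generation) else 0,
    late = list(
      occupancy = mean(keep$n_individuals) / object$config$ns,
      n_strains = mean(keep$n_strains),
      births_per_generation = mean(keep$births),
      contest_deaths_per_generation = mean(keep$deaths_contest),
      lifespan_deaths_per_generation = mean(keep$deaths_lifespan),
      mutations_per_generation = mean(keep$mutations)),
    per_generation = s)
  class(out) <- "summary.iteem_sim"
  out
}

#' @export
print.summary.iteem_sim <- function(x, ...) {
  print(x$config)
  cat(sprintf("Ran %d generation(s)%s\n", x$generations_run,
              if (x$extinct) " (extinct)" else ""))
  l <- x$late
  cat(sprintf("Late-time means: occupancy %.4f | strains %.1f | births/gen %.1f\n",
              l$occupancy, l$n_strains, l$births_per_generation))
  cat(sprintf("  deaths/gen: %.1f contest, %.1f lifespan | established mutants/gen %.3f\n",
              l$contest_deaths_per_generation,
              l$lifespan_deaths_per_generation, l$mutations_per_generation))
  invisible(x)
}

#' Plot simulation trajectories
#'
#' Base-graphics view of occupancy and strain richness over time.
#'
#' @param x an `iteem_sim` object.
#' @param ... passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.iteem_sim <- function(x, ...) {
  s <- x$summary
  if (nrow(s) == 0) stop("nothing to plot: the run produced no generations")
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1, 1))
  on.exit(graphics::par(op))
  graphics::plot(s$generation, s$n_individuals / x$config$ns, type = "l",
                 xlab = "generation", ylab = "occupancy", ylim = c(0, 1), ...)
  graphics::plot(s$generation, s$n_strains, type = "l",
                 xlab = "generation", ylab = "strain richness", ...)
  invisible(x)
}

#' Neutral contest outcomes
#'
#' Draws `n` contests with the neutral model's fair coin (challenger
#' survival probability 0.5, the same decision used for every encounter in
#' neutral mode) and returns the number of challenger wins.
#'
#' @param n number of contests.
#' @param p challenger survival probability (0.5 for the neutral model).
#' @return Integer number of challenger wins.
#' @export
neutral_contest <- function(n, p = 0.5) {
  stopifnot(n >= 1, p >= 0, p <= 1)
  .contest_wins(p, as.integer(n))
}

#' Low-level stepping interface
#'
#' `engine_start()` builds a live engine (an external pointer) from a
#' configuration, seeding it with the founder strain or a custom community;
#' `engine_trial()` performs one replication trial, `engine_death_step()`
#' one death step, `engine_next_generation()` advances the generation
#' counter, and `engine_state()` returns the full community state
#' (abundances, interaction matrix, per-strain competitive ability and
#' replication probability, site occupancy).  Intended for tests and
#' instrumented experiments; [run_simulation()] is the fast path.
#'
#' @inheritParams run_simulation
#' @return `engine_start()` an external pointer; `engine_trial()` an integer
#'   event code (-1 empty community, 0 no replication, 1 colonised an empty
#'   site, 2 offspring won its contest, 3 offspring lost; +10 when the
#'   offspring was a mutant); `engine_death_step()` the number of
#'   individuals removed; `engine_state()` a list.
#' @export
engine_start <- function(cfg, init = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  ptr <- .new_engine(cfg)
  if (is.null(init)) {
    .eng_init_founder(ptr)
  } else {
    im <- init$matrix
    if (inherits(im, "interaction_matrix")) im <- im$entries
    .eng_init_custom(ptr, im, as.integer(init$abundance),
                     if (is.null(init$r)) NULL else as.numeric(init$r))
  }
  ptr
}

#' @rdname engine_start
#' @param engine an engine pointer from `engine_start()`.
#' @export
engine_trial <- function(engine) .eng_trial(engine)

#' @rdname engine_start
#' @export
engine_death_step <- function(engine) .eng_death_step(engine)

#' @rdname engine_start
#' @export
engine_next_generation <- function(engine) invisible(.eng_advance_time(engine))

#' @rdname engine_start
#' @export
engine_state <- function(engine) .eng_state(engine)
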
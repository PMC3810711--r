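#' Configuration for the evolutionary-wrapper feature selection
#'
#' The wrapper evolves bitmask individuals over a candidate feature set;
#' an individual's fitness is the multiclass accuracy of a random forest
#' trained on the selected features (estimated by stratified k-fold
#' cross-validation or out-of-bag), minus a per-feature size penalty that
#' breaks accuracy ties toward smaller panels.
#'
#' Defaults follow the full study protocol (6 runs of 100 000 fitness
#' evaluations); pass far smaller `iterations`/`runs` for interactive or
#' test-scale work (e.g. `iterations = 2000`, `population_size = 40`).
#'
#' @param population_size individuals per generation.
#' @param iterations fitness-evaluation budget per run.
#' @param runs number of independent runs; the automatic panel is the
#'   union of per-run best feature sets.
#' @param mutation_rate per-bit mutation probability; `NULL` = 1/L.
#' @param crossover_rate probability of uniform crossover per offspring.
#' @param elitism individuals copied unchanged each generation (< population).
#' @param size_penalty fitness penalty per selected feature.
#' @param fitness_folds integer >= 2 for stratified k-fold CV, or `"oob"`
#'   for out-of-bag accuracy from a single forest.
#' @param seeds one RNG seed per run; `NULL` derives them from `seed`.
#' @param seed base seed used when `seeds` is `NULL`.
#' @param trees random-forest tree count for fitness evaluation.
#' @param tournament_size tournament selection size.
#' @export
ea_config <- function(population_size = 40L, iterations = 100000L, runs = 6L,
                      mutation_rate = NULL, crossover_rate = 0.7,
                      elitism = 1L, size_penalty = 0.001,
                      fitness_folds = 5L, seeds = NULL, seed = 1L,
                      trees = 100L, tournament_size = 3L) {
  if (population_size < 2L) stop_fmt("population_size must be >= 2")
  if (elitism >= population_size) stop_fmt("elitism must be < population_size")
  if (!identical(fitness_folds, "oob") && (!is_count(fitness_folds) || fitness_folds < 2))
    stop_fmt("fitness_folds must be an integer >= 2 or \"oob\"")
  seeds <- seeds %||% vapply(seq_len(runs), function(r) derive_seed(seed, r), 0L)
  if (length(seeds) != runs) stop_fmt("need one seed per run")
  structure(list(population_size = as.integer(population_size),
                 iterations = as.integer(iterations), runs = as.integer(runs),
                 mutation_rate = mutation_rate, crossover_rate = crossover_rate,
                 elitism = as.integer(elitism), size_penalty = size_penalty,
                 fitness_folds = fitness_folds, seeds = as.integer(seeds),
                 trees = as.integer(trees),
                 tournament_size = as.integer(tournament_size)),
            class = "ea_config")
}

stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (cl in levels(y)) {
    idx <- sample(which(y == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

# Fitness of one bitmask: RF accuracy estimate minus size penalty.
# Deterministic within a run because the run's RNG stream drives both the
# fold assignment (fixed once per run) and the forests.
make_fitness <- function(x, y, cfg) {
  fold <- if (!identical(cfg$fitness_folds, "oob"))
    stratified_folds(y, cfg$fitness_folds)
  majority <- max(table(y)) / length(y)
  cache <- new.env(parent = emptyenv())
  evals <- 0L
  list(
    fn = function(mask) {
      # every request spends budget; the cache only avoids refitting, so
      # revisited masks keep the per-run fitness deterministic
      evals <<- evals + 1L
      key <- rawToChar(as.raw(44L + mask))
      hit <- get0(key, envir = cache, inherits = FALSE)
      if (!is.null(hit)) return(hit)
      p <- sum(mask)
      acc <- if (p == 0L) {
        majority
      } else if (identical(cfg$fitness_folds, "oob")) {
        rf <- randomForest::randomForest(x[, mask == 1L, drop = FALSE], y,
                                         ntree = cfg$trees)
        mean(rf$predicted == y)
      } else {
        pred <- factor(rep(NA_character_, length(y)), levels = levels(y))
        for (f in seq_len(cfg$fitness_folds)) {
          tr <- fold != f
          rf <- randomForest::randomForest(x[tr, mask == 1L, drop = FALSE], y[tr],
                                           ntree = cfg$trees)
          pred[!tr] <- stats::predict(rf, x[!tr, mask == 1L, drop = FALSE])
        }
        mean(pred == y)
      }
      fit <- acc - cfg$size_penalty * p
      assign(key, fit, envir = cache)
      fit
    },
    n_evals = function() evals
  )
}

ea_run <- function(x, y, cfg, run_seed) {
  L <- ncol(x)
  pm <- cfg$mutation_rate %||% (1 / L)
  with_seed(run_seed, {
    fitness <- make_fitness(x, y, cfg)
    pop <- matrix(as.integer(stats::runif(cfg$population_size * L) < 0.5),
                  nrow = cfg$population_size)
    fit <- apply(pop, 1L, fitness$fn)
    history <- max(fit)
    while (fitness$n_evals() < cfg$iterations) {
      ord <- order(fit, decreasing = TRUE)
      elite <- pop[ord[seq_len(cfg$elitism)], , drop = FALSE]
      tournament <- function() {
        cand <- sample.int(cfg$population_size, cfg$tournament_size, replace = TRUE)
        pop[cand[which.max(fit[cand])], ]
      }
      children <- matrix(0L, cfg$population_size - cfg$elitism, L)
      for (i in seq_len(nrow(children))) {
        p1 <- tournament()
        child <- if (stats::runif(1) < cfg$crossover_rate) {
          p2 <- tournament()
          take <- stats::runif(L) < 0.5
          ifelse(take, p1, p2)
        } else p1
        flip <- stats::runif(L) < pm
        children[i, ] <- as.integer(xor(child == 1L, flip))
      }
      pop <- rbind(elite, children)
      fit <- apply(pop, 1L, fitness$fn)
      history <- c(history, max(fit))
    }
    best <- which.max(fit)
    list(mask = pop[best, ], fitness = fit[[best]], history = history,
         n_evals = fitness$n_evals())
  })
}

#' Evolutionary-wrapper automatic feature selection
#'
#' Runs `cfg$runs` independent evolutionary searches over bitmasks of the
#' candidate proteins (typically the preselected list), each wrapped
#' around a random-forest classifier of the clinical groups (the
#' multiclass case is supported directly). Each run returns its best
#' individual's feature set; the automatic panel is the union across
#' runs. Fully reproducible from `cfg$seeds`.
#'
#' @param m an `intensity_matrix` (restrict with `proteins`).
#' @param design a `study_design`; classes are the `group` column.
#' @param cfg an [ea_config()].
#' @param proteins candidate protein ids; default all matrix rows.
#' @return A `biomarker_panel` with provenance `"automatic"`; attribute
#'   `"runs"` holds per-run best masks, fitnesses and best-fitness
#'   trajectories.
#' @export
ea_wrapper_select <- function(m, design, cfg = ea_config(), proteins = NULL) {
  stopifnot(inherits(m, "intensity_matrix"), inherits(cfg, "ea_config"))
  design <- study_design(as.data.frame(design))
  proteins <- proteins %||% rownames(m$values)
  missing <- setdiff(proteins, rownames(m$values))
  if (length(missing))
    stop_fmt("unknown protein id(s): %s", paste(missing, collapse = ", "))
  x <- t(m$values[proteins, , drop = FALSE])
  y <- factor(design$group[match(rownames(x), design$sample_id)])
  if (anyNA(y)) stop_fmt("design lacks rows for some matrix samples")
  if (nlevels(y) < 2L) stop_fmt("need at least 2 classes")
  if (any(table(y) < 2L))
    stop_fmt("degenerate class with fewer than 2 samples: %s",
             paste(names(which(table(y) < 2L)), collapse = ", "))
  runs <- lapply(seq_len(cfg$runs), function(r) ea_run(x, y, cfg, cfg$seeds[[r]]))
  sel <- sort(unique(unlist(lapply(runs, function(r) which(r$mask == 1L)))))
  panel <- biomarker_panel(proteins[sel], "automatic")
  attr(panel, "runs") <- runs
  panel
}
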
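#' Piecewise-constant effective population size trajectory
#'
#' Describes Ne changes back in time along a single lineage, e.g. the
#' stepwise trajectories that sequential-coalescent methods infer from a
#' single diploid genome.
#'
#' @param breakpoints Times in generations before present, strictly
#'   ascending; may be empty for a constant size.
#' @param ne_values Diploid effective sizes per epoch; one more value than
#'   breakpoints, ordered from the present backwards.
#' @return An object of class `piecewise_ne`.
#' @examples
#' piecewise_ne(c(1000, 5000), c(2000, 10000, 30000))
#' @export
piecewise_ne <- function(breakpoints, ne_values) {
  breakpoints <- as.numeric(breakpoints)
  ne_values <- as.numeric(ne_values)
  if (length(ne_values) != length(breakpoints) + 1L)
    stop("need exactly one more Ne value than breakpoints", call. = FALSE)
  if (length(breakpoints) && (any(breakpoints <= 0) ||
      is.unsorted(breakpoints, strictly = TRUE)))
    stop("breakpoints must be positive and strictly ascending",
         call. = FALSE)
  if (any(ne_values <= 0)) stop("all Ne values must be > 0", call. = FALSE)
  structure(list(breakpoints = breakpoints, ne_values = ne_values),
            class = "piecewise_ne")
}

# Ne at time t (generations before present) under a piecewise trajectory
ne_at <- function(traj, t) {
  traj$ne_values[findInterval(t, traj$breakpoints) + 1L]
}

#' Demographic model: population tree, sizes, and migration bands
#'
#' Represents a rooted binary population phylogeny with per-branch
#' diploid effective sizes and optional directed migration bands between
#' coexisting branches. Time is stored internally in generations before
#' present; years appear only at I/O boundaries via `gen_time`.
#'
#' Each population is a branch of the tree: leaves exist from the present
#' (time 0) back to the split where they merge into their parent; an
#' internal population begins at the split time of its two children.
#' A migration band `source -> target` is read in forward time; its total
#' rate `m_tot` is spread uniformly over the interval during which the two
#' branches coexist (see [migration_convert()]).
#'
#' @param populations A data.frame with columns `name`, `parent` (`NA` for
#'   the root) and `ne` (diploid individuals).
#' @param split_years Named numeric: for each internal population, the time
#'   (years before present) at which its two children merge into it.
#' @param gen_time Years per generation used to convert `split_years`.
#' @param migration_bands Optional data.frame with columns `source`,
#'   `target`, `m_tot` (forward-time direction; total rate over the band).
#' @param trajectories Optional named list of [piecewise_ne()] objects for
#'   terminal branches, overriding their constant `ne` near the present.
#' @param name Optional model name.
#' @return An object of class `demographic_model`.
#' @examples
#' m <- demographic_model(
#'   populations = data.frame(
#'     name = c("A", "B", "AB"), parent = c("AB", "AB", NA),
#'     ne = c(10000, 10000, 20000)),
#'   split_years = c(AB = 30000), gen_time = 3)
#' m
#' @export
demographic_model <- function(populations, split_years, gen_time = 3,
                              migration_bands = NULL, trajectories = NULL,
                              name = "model") {
  stopifnot(is.data.frame(populations),
            all(c("name", "parent", "ne") %in% names(populations)))
  pop <- data.frame(name = as.character(populations$name),
                    parent = as.character(populations$parent),
                    ne = as.numeric(populations$ne),
                    stringsAsFactors = FALSE)
  if (anyDuplicated(pop$name)) stop("duplicate population names",
                                    call. = FALSE)
  root <- pop$name[is.na(pop$parent)]
  if (length(root) != 1L)
    stop("model must have exactly one root population", call. = FALSE)
  if (!all(pop$parent[!is.na(pop$parent)] %in% pop$name))
    stop("unknown parent population", call. = FALSE)
  if (any(pop$ne <= 0)) stop("all Ne must be > 0", call. = FALSE)

  n_child <- table(factor(pop$parent, levels = pop$name))
  leaves <- pop$name[n_child[pop$name] == 0]
  internals <- setdiff(pop$name, leaves)
  if (!all(n_child[internals] == 2L))
    stop("every internal population must have exactly two children",
         call. = FALSE)
  if (!setequal(names(split_years), internals))
    stop("'split_years' must name exactly the internal populations",
         call. = FALSE)
  if (gen_time <= 0) stop("'gen_time' must be > 0", call. = FALSE)

  t_start <- setNames(numeric(nrow(pop)), pop$name)
  t_start[internals] <- as.numeric(split_years[internals]) / gen_time
  # strict root-ward ordering along every parent-child edge
  for (i in seq_len(nrow(pop))) {
    p <- pop$parent[i]
    if (!is.na(p) && t_start[p] <= t_start[pop$name[i]])
      stop(sprintf(
        "split time of '%s' must be strictly older than that of child '%s'",
        p, pop$name[i]), call. = FALSE)
  }
  pop$t_start <- unname(t_start[pop$name])
  # end of existence (merge into parent); Inf for root
  pop$t_end <- ifelse(is.na(pop$parent), Inf,
                      unname(t_start[pop$parent]))

  bands <- NULL
  if (!is.null(migration_bands) && nrow(migration_bands)) {
    stopifnot(all(c("source", "target", "m_tot") %in%
                    names(migration_bands)))
    bands <- data.frame(source = as.character(migration_bands$source),
                        target = as.character(migration_bands$target),
                        m_tot = as.numeric(migration_bands$m_tot),
                        stringsAsFactors = FALSE)
    if (any(bands$m_tot < 0)) stop("m_tot must be >= 0", call. = FALSE)
    if (!all(c(bands$source, bands$target) %in% pop$name))
      stop("migration band names unknown", call. = FALSE)
    idx <- match(bands$source, pop$name)
    jdx <- match(bands$target, pop$name)
    bands$t_lo <- pmax(pop$t_start[idx], pop$t_start[jdx])
    bands$t_hi <- pmin(pop$t_end[idx], pop$t_end[jdx])
    if (any(bands$t_hi <= bands$t_lo))
      stop("migration band between populations that never coexist",
           call. = FALSE)
    dur <- bands$t_hi - bands$t_lo
    bands$m <- ifelse(is.finite(dur), bands$m_tot / dur, 0)
  }

  if (!is.null(trajectories)) {
    if (is.null(names(trajectories)) ||
        !all(names(trajectories) %in% leaves))
      stop("trajectories must be named after terminal populations",
           call. = FALSE)
    for (tr in trajectories) stopifnot(inherits(tr, "piecewise_ne"))
  }

  structure(list(pop = pop, root = root, leaves = leaves,
                 gen_time = gen_time, bands = bands,
                 trajectories = trajectories, name = name),
            class = "demographic_model")
}

#' @export
print.demographic_model <- function(x, ...) {
  cat(sprintf("Demographic model '%s': %d populations (%d sampled leaves)\n",
              x$name, nrow(x$pop), length(x$leaves)))
  cat(sprintf("  generation time: %g years\n", x$gen_time))
  int <- x$pop[is.finite(x$pop$t_start) & x$pop$t_start > 0, ]
  if (nrow(int)) {
    int <- int[order(int$t_start), ]
    cat("  splits (kya):",
        paste(sprintf("%s=%.1f", int$name,
                      int$t_start * x$gen_time / 1000), collapse = ", "),
        "\n")
  }
  if (!is.null(x$bands))
    cat(sprintf("  migration bands: %d\n", nrow(x$bands)))
  invisible(x)
}

#' Read or write a demographic model config file
#'
#' Models are serialized as YAML with keys `name`, `generation_time`
#' (years), `populations` (list of `name`/`parent`/`ne` entries, `ne` in
#' diploid individuals), `splits` (internal population -> years before
#' present) and optionally `migration_bands` (list of
#' `source`/`target`/`m_tot`, forward-time direction). A bundled file
#' `fig5a.yaml` (see `system.file("extdata", package = "canidemog")`)
#' encodes the seven-canid model with dog/wolf reciprocal monophyly;
#' `regional.yaml` and `isw_source.yaml` encode the two alternatives.
#'
#' @param path Path to a YAML model file.
#' @return [read_demographic_model()] returns a `demographic_model`;
#'   [write_demographic_model()] returns `path` invisibly.
#' @export
read_demographic_model <- function(path) {
  if (!file.exists(path))
    stop(sprintf("model file not found: '%s'", path), call. = FALSE)
  y <- yaml::read_yaml(path)
  pops <- do.call(rbind, lapply(y$populations, function(p)
    data.frame(name = p$name,
               parent = if (is.null(p$parent)) NA_character_ else p$parent,
               ne = as.numeric(p$ne), stringsAsFactors = FALSE)))
  splits <- unlist(y$splits)
  bands <- NULL
  if (!is.null(y$migration_bands) && length(y$migration_bands))
    bands <- do.call(rbind, lapply(y$migration_bands, function(b)
      data.frame(source = b$source, target = b$target,
                 m_tot = as.numeric(b$m_tot), stringsAsFactors = FALSE)))
  demographic_model(pops, splits,
                    gen_time = as.numeric(y$generation_time),
                    migration_bands = bands,
                    name = if (is.null(y$name)) "model" else y$name)
}

#' @rdname read_demographic_model
#' @param model A `demographic_model` object.
#' @export
write_demographic_model <- function(model, path) {
  stopifnot(inherits(model, "demographic_model"))
  pops <- lapply(seq_len(nrow(model$pop)), function(i) {
    p <- list(name = model$pop$name[i], ne = model$pop$ne[i])
    if (!is.na(model$pop$parent[i])) p$parent <- model$pop$parent[i]
    p
  })
  int <- model$pop[model$pop$t_start > 0, ]
  splits <- as.list(setNames(int$t_start * model$gen_time, int$name))
  y <- list(name = model$name, generation_time = model$gen_time,
            populations = pops, splits = splits)
  if (!is.null(model$bands))
    y$migration_bands <- lapply(seq_len(nrow(model$bands)), function(i)
      list(source = model$bands$source[i], target = model$bands$target[i],
           m_tot = model$bands$m_tot[i]))
  yaml::write_yaml(y, path)
  invisible(path)
}

#' Load one of the bundled canid demographic models
#'
#' @param which One of `"fig5a"` (dog/wolf reciprocal monophyly, the
#'   best-supported model), `"regional"` (each dog lineage sister to the
#'   wolf from its geographic region) or `"isw_source"` (all dogs derived
#'   from the Israeli wolf lineage).
#' @param migration If `FALSE` (default) the model is returned without its
#'   migration bands, the configuration used for the clean-split analyses;
#'   if `TRUE` the low-rate default bands in the config file are kept.
#' @return A `demographic_model`.
#' @examples
#' canid_model("fig5a")
#' @export
canid_model <- function(which = c("fig5a", "regional", "isw_source"),
                        migration = FALSE) {
  which <- match.arg(which)
  path <- system.file("extdata", paste0(which, ".yaml"),
                      package = "canidemog", mustWork = TRUE)
  m <- read_demographic_model(path)
  if (!migration) m$bands <- NULL
  m
}

# --- internal: compile a model into an epoch schedule for the simulator ---
#
# Returns a list with:
#   pop_names, n_pop
#   epochs: list of (t_end, ne [1/pop; Inf if inactive], merge_from,
#           merge_to [pop indices merged at epoch *start*],
#           band_target, band_source, band_rate)
compile_model <- function(model) {
  pop <- model$pop
  P <- nrow(pop)
  idx <- setNames(seq_len(P), pop$name)
  bounds <- sort(unique(pop$t_start[pop$t_start > 0]))
  if (!is.null(model$trajectories))
    bounds <- sort(unique(c(bounds, unlist(
      lapply(model$trajectories, `[[`, "breakpoints")))))
  t_lo <- c(0, bounds)
  t_hi <- c(bounds, Inf)
  epochs <- vector("list", length(t_lo))
  for (e in seq_along(t_lo)) {
    lo <- t_lo[e]; hi <- t_hi[e]
    alive <- pop$t_start <= lo & pop$t_end > lo
    ne <- rep(Inf, P)
    ne[alive] <- pop$ne[alive]
    if (!is.null(model$trajectories))
      for (nm in names(model$trajectories))
        if (alive[idx[nm]])
          ne[idx[nm]] <- ne_at(model$trajectories[[nm]], lo)
    merge_i <- which(abs(pop$t_end - lo) < 1e-9 & pop$t_end > 0)
    band_t <- integer(0); band_s <- integer(0); band_r <- numeric(0)
    if (!is.null(model$bands)) {
      act <- model$bands$t_lo <= lo & model$bands$t_hi > lo &
        model$bands$m > 0
      if (any(act)) {
        band_t <- idx[model$bands$target[act]]
        band_s <- idx[model$bands$source[act]]
        band_r <- model$bands$m[act]
      }
    }
    epochs[[e]] <- list(
      t_end = hi, ne = ne,
      merge_from = merge_i,
      merge_to = if (length(merge_i)) idx[pop$parent[merge_i]] else integer(0),
      band_target = band_t, band_source = band_s, band_rate = band_r)
  }
  list(pop_names = pop$name, n_pop = P, idx = idx, epochs = epochs)
}
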
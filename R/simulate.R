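#' Simulate one genealogy under the structured coalescent
#'
#' Event-driven, continuous-time simulation backwards in time under a
#' [demographic_model()]: within each epoch, every pair of lineages in a
#' population of diploid size Ne coalesces at rate `1/(2*Ne)`, and each
#' lineage in the target population of an active migration band migrates
#' (backwards) to the band's source at the band's per-generation rate. At
#' split times the daughter lineage sets merge into the parent population.
#' Simulation ends at the grand most recent common ancestor.
#'
#' @param model A `demographic_model`.
#' @param samples Named integer vector: number of sampled lineages per
#'   leaf population (a diploid contributes 2). Default: 2 lineages from
#'   every leaf.
#' @param seed Optional integer seed; if `NULL`, the current RNG stream is
#'   used (useful when simulating many replicates).
#' @return An object of class `genealogy`: a list with `parent` (node id
#'   of each node's parent; 0 for the root), `time` (node times in
#'   generations), `leaf_pop` (population of each sampled leaf),
#'   `tbl` (total branch length in generations) and `tmrca`.
#' @examples
#' m <- canid_model("fig5a")
#' g <- simulate_genealogy(m, c(CRW = 2), seed = 1)
#' g$tmrca
#' @export
simulate_genealogy <- function(model, samples = NULL, seed = NULL) {
  stopifnot(inherits(model, "demographic_model"))
  plan <- compile_model(model)
  if (is.null(samples)) samples <- setNames(
    rep(2L, length(model$leaves)), model$leaves)
  if (is.null(names(samples)) || !all(names(samples) %in% model$leaves))
    stop("'samples' must be named after leaf populations", call. = FALSE)
  if (!is.null(seed)) set.seed(as.integer(seed))
  lin_pop <- rep(plan$idx[names(samples)], times = samples)
  g <- sim_coal_once(plan, lin_pop)
  g$leaf_pop <- rep(names(samples), times = samples)
  g
}

# Deterministic per-locus seed: a multiplicative hash of (seed, locus)
# keeps locus streams reproducible for any subset of loci while making
# the streams of different master seeds unrelated (a plain seed + index
# scheme would share almost all locus streams between nearby seeds).
# All products stay below 2^53, so the arithmetic is exact in doubles.
locus_seed <- function(seed, i) {
  h <- (abs(seed) %% 2147483647) * 48271 + i * 2654435761
  as.integer(h %% 2147483647)
}

# core event loop; lin_pop: integer population index per sampled lineage
sim_coal_once <- function(plan, lin_pop) {
  n <- length(lin_pop)
  if (n < 2L) stop("need at least 2 lineages", call. = FALSE)
  n_nodes <- 2L * n - 1L
  parent <- integer(n_nodes)
  ntime <- numeric(n_nodes)
  active <- seq_len(n)     # node ids of live lineages
  apop <- as.integer(lin_pop)
  nxt <- n + 1L
  t <- 0
  for (ep in plan$epochs) {
    # population merges at epoch start (backwards in time)
    if (length(ep$merge_from))
      for (j in seq_along(ep$merge_from))
        apop[apop == ep$merge_from[j]] <- ep$merge_to[j]
    if (length(active) == 1L) next
    t_end <- ep$t_end
    nb <- length(ep$band_rate)
    repeat {
      k <- tabulate(apop, nbins = plan$n_pop)
      crate <- k * (k - 1L) / (4 * ep$ne)   # 0 where inactive (ne = Inf)
      mrate <- if (nb) k[ep$band_target] * ep$band_rate else numeric(0)
      total <- sum(crate) + sum(mrate)
      if (total <= 0) { t <- t_end; break }
      dt <- stats::rexp(1L, total)
      if (t + dt >= t_end) { t <- t_end; break }
      t <- t + dt
      u <- stats::runif(1L) * total
      cs <- cumsum(c(crate, mrate))
      ev <- which(u <= cs)[1L]
      if (ev <= plan$n_pop) {
        # coalescence in population ev
        here <- active[apop == ev]
        pair <- if (length(here) == 2L) here else sample(here, 2L)
        node <- nxt; nxt <- nxt + 1L
        ntime[node] <- t
        parent[pair] <- node
        drop <- match(pair, active)
        active <- c(active[-drop], node)
        apop <- c(apop[-drop], ev)
        if (length(active) == 1L) break
      } else {
        b <- ev - plan$n_pop
        here <- which(apop == ep$band_target[b])
        pick <- if (length(here) == 1L) here else sample(here, 1L)
        apop[pick] <- ep$band_source[b]
      }
    }
    if (length(active) == 1L && !is.finite(t_end)) break
  }
  if (length(active) != 1L)
    stop("lineages failed to reach a common ancestor; malformed model",
         call. = FALSE)
  bl <- ntime[parent[-n_nodes]] - ntime[-n_nodes]
  structure(list(parent = parent, time = ntime, n_leaves = n,
                 tbl = sum(bl), tmrca = ntime[n_nodes]),
            class = "genealogy")
}

# leaves carrying a mutation on the branch above node `b`
descendant_matrix <- function(parent, n_leaves) {
  n_nodes <- length(parent)
  d <- matrix(FALSE, n_nodes, n_leaves)
  d[cbind(seq_len(n_leaves), seq_len(n_leaves))] <- TRUE
  for (i in seq_len(n_nodes - 1L))   # children are created before parents
    d[parent[i], ] <- d[parent[i], ] | d[i, ]
  d
}

#' Simulate a multi-locus dataset of unlinked neutral loci
#'
#' For each locus one genealogy is drawn with [simulate_genealogy()] and
#' mutations are placed by a Poisson process with rate
#' `mu * locus_length * total branch length`, under the infinite-sites
#' assumption within the locus (every mutation hits a new site; no
#' intra-locus recombination). Each sampled population contributes one
#' diploid genotype (its two lineages); the derived allele is the mutant.
#'
#' Random-number streams are per locus (derived from `seed` plus the locus
#' index), so any subset of loci reproduces exactly regardless of how the
#' remaining loci are handled.
#'
#' @inheritParams simulate_genealogy
#' @param n_loci Number of unlinked loci (default 16434, the size of the
#'   neutral-locus set the model emulates).
#' @param locus_length Locus length in bp (default 1000).
#' @param mu Mutation rate per site per generation.
#' @param seed Integer seed (required; drives the per-locus streams).
#' @return A [locus_set()] with one diploid sample per sampled population.
#' @examples
#' m <- canid_model("fig5a")
#' ls <- simulate_dataset(m, n_loci = 50, mu = 1e-8, seed = 1,
#'                        samples = c(BOX = 2, CRW = 2, GLJ = 2))
#' ls
#' @export
simulate_dataset <- function(model, n_loci = 16434, locus_length = 1000,
                             mu = 1e-8, seed, samples = NULL) {
  stopifnot(inherits(model, "demographic_model"))
  if (n_loci <= 0 || locus_length <= 0)
    stop("'n_loci' and 'locus_length' must be > 0", call. = FALSE)
  if (mu < 0) stop("'mu' must be >= 0", call. = FALSE)
  if (missing(seed) || is.null(seed))
    stop("'seed' is required for reproducible simulation", call. = FALSE)
  plan <- compile_model(model)
  if (is.null(samples)) samples <- setNames(
    rep(2L, length(model$leaves)), model$leaves)
  if (is.null(names(samples)) || !all(names(samples) %in% model$leaves))
    stop("'samples' must be named after leaf populations", call. = FALSE)
  if (!all(samples == 2L))
    stop("one diploid (2 lineages) per sampled population is required",
         call. = FALSE)
  sample_names <- names(samples)
  lin_pop <- rep(plan$idx[sample_names], each = 2L)
  lin_of <- rep(seq_along(sample_names), each = 2L)
  n_lin <- length(lin_pop)
  # lineage -> sample aggregation matrix (dosage = carriers among the pair)
  agg <- matrix(0L, n_lin, length(sample_names),
                dimnames = list(NULL, sample_names))
  agg[cbind(seq_len(n_lin), lin_of)] <- 1L

  geno_list <- vector("list", n_loci)
  site_list <- vector("list", n_loci)
  for (i in seq_len(n_loci)) {
    set.seed(locus_seed(as.integer(seed), i))
    g <- sim_coal_once(plan, lin_pop)
    lambda <- mu * locus_length * g$tbl
    if (lambda > locus_length)
      stop(sprintf(paste0(
        "infinite-sites violation at locus %d: expected %.1f mutations ",
        "exceed locus length %d; reduce 'mu' or increase 'locus_length'"),
        i, lambda, locus_length), call. = FALSE)
    n_mut <- stats::rpois(1L, lambda)
    if (n_mut == 0L) next
    if (n_mut > locus_length)
      stop(sprintf(
        "infinite-sites violation at locus %d: %d mutations on %d sites",
        i, n_mut, locus_length), call. = FALSE)
    n_nodes <- 2L * n_lin - 1L
    bl <- g$time[g$parent[-n_nodes]] - g$time[-n_nodes]
    br <- sample.int(n_nodes - 1L, n_mut, replace = TRUE, prob = bl)
    pos <- sort(sample.int(locus_length, n_mut)) - 1L
    desc <- descendant_matrix(g$parent, n_lin)
    carr <- desc[br, , drop = FALSE]                # mutations x lineages
    gm <- (carr * 1L) %*% agg
    storage.mode(gm) <- "integer"
    geno_list[[i]] <- gm
    site_list[[i]] <- data.frame(locus = i, pos = pos)
  }
  keep <- !vapply(geno_list, is.null, logical(1))
  geno <- do.call(rbind, c(geno_list[keep],
                           list(matrix(integer(0), 0, length(sample_names),
                                       dimnames = list(NULL, sample_names)))))
  site <- if (any(keep)) do.call(rbind, site_list[keep]) else
    data.frame(locus = integer(0), pos = integer(0))
  locus_set(geno, site, n_loci = n_loci, locus_length = locus_length)
}

#' Simulate a single diploid genome under a piecewise-Ne trajectory
#'
#' Single-population special case of [simulate_dataset()]: two lineages
#' from one population whose diploid size follows a [piecewise_ne()]
#' trajectory backwards in time. This emulates datasets generated under a
#' stepwise ancestral-size history, e.g. one inferred from a single genome
#' by a sequential-coalescent method.
#'
#' @param trajectory A [piecewise_ne()] object.
#' @inheritParams simulate_dataset
#' @param sample_name Name for the simulated diploid (default "sample").
#' @return A [locus_set()] with one sample.
#' @export
simulate_trajectory_genome <- function(trajectory, n_loci = 16434,
                                       locus_length = 1000, mu = 1e-8,
                                       seed, sample_name = "sample") {
  stopifnot(inherits(trajectory, "piecewise_ne"))
  pops <- data.frame(name = sample_name, parent = NA_character_,
                     ne = trajectory$ne_values[1], stringsAsFactors = FALSE)
  m <- demographic_model(pops, split_years = setNames(numeric(0),
                                                      character(0)),
                         gen_time = 1,
                         trajectories = setNames(list(trajectory),
                                                 sample_name),
                         name = "trajectory")
  simulate_dataset(m, n_loci = n_loci, locus_length = locus_length,
                   mu = mu, seed = seed,
                   samples = setNames(2L, sample_name))
}

#' Simulate a read-depth track over a copy-number profile
#'
#' Per-base sequencing depth is drawn as Poisson with mean
#' `copy * haploid_mean_depth`. A diploid control track (copy 2
#' everywhere) of the same length is emitted alongside, providing the
#' normalization baseline for [copy_number_from_depth()].
#'
#' @param copy_profile Integer vector of per-base copy numbers (>= 0).
#' @param haploid_mean_depth Mean reads per base per haploid copy (> 0).
#' @param window Window size in bp for the window-averaged track.
#' @param seed Integer seed.
#' @param contig Name for the pseudo-contig.
#' @return An object of class `depth_track`: per-base `depth` and `copy`,
#'   window means (0-based half-open intervals) and a `control` list with
#'   the control depths and their mean.
#' @examples
#' tr <- simulate_depth_track(rep(2L, 2000), 15, window = 500, seed = 1)
#' tr$control$mean
#' @export
simulate_depth_track <- function(copy_profile, haploid_mean_depth,
                                 window = 1000, seed, contig = "target") {
  if (!length(copy_profile))
    stop("'copy_profile' must be non-empty", call. = FALSE)
  if (any(copy_profile < 0)) stop("copy numbers must be >= 0",
                                  call. = FALSE)
  if (haploid_mean_depth <= 0)
    stop("'haploid_mean_depth' must be > 0", call. = FALSE)
  if (missing(seed) || is.null(seed))
    stop("'seed' is required", call. = FALSE)
  set.seed(as.integer(seed))
  L <- length(copy_profile)
  depth <- stats::rpois(L, copy_profile * haploid_mean_depth)
  control <- stats::rpois(L, 2 * haploid_mean_depth)
  w0 <- seq(0L, L - 1L, by = window)
  w1 <- pmin(w0 + window, L)
  wmean <- vapply(seq_along(w0), function(i)
    mean(depth[(w0[i] + 1L):w1[i]]), numeric(1))
  structure(list(contig = contig, depth = depth,
                 copy = as.integer(copy_profile),
                 windows = data.frame(start = w0, end = w1, mean = wmean),
                 control = list(depth = control, mean = mean(control))),
            class = "depth_track")
}

#' @export
print.depth_track <- function(x, ...) {
  cat(sprintf("Depth track '%s': %d bp, mean depth %.1f (control %.1f)\n",
              x$contig, length(x$depth), mean(x$depth), x$control$mean))
  invisible(x)
}
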
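# Independent oracles and fixture builders used across the test files.

# Closed-form E[TMRCA] for 2 lineages under piecewise-constant diploid Ne:
# integrate the survival function of the time-inhomogeneous exponential
# epoch by epoch. breaks: epoch start times (generations, first must be 0),
# ne: diploid sizes per epoch (last epoch extends to infinity).
# E[T2] = integral of the survival function S(t); within epoch k of
# length dt and size Ne, S multiplies by exp(-dt/(2 Ne)) and contributes
# S_start * 2 Ne * (1 - exp(-dt/(2 Ne))) to the integral.
expected_t2_piecewise <- function(breaks, ne) {
  stopifnot(breaks[1] == 0, length(ne) == length(breaks))
  surv <- 1
  e_t2 <- 0
  for (k in seq_along(ne)) {
    dt <- (if (k < length(ne)) breaks[k + 1] else Inf) - breaks[k]
    decay <- exp(-dt / (2 * ne[k]))
    e_t2 <- e_t2 + surv * 2 * ne[k] * (1 - decay)
    surv <- surv * decay
  }
  e_t2
}

# The Ne history seen backwards in time by a single leaf population of a
# demographic model (no migration): follow the chain of ancestors.
ne_path_of_leaf <- function(model, leaf) {
  pop <- model$pop
  breaks <- numeric(0); ne <- numeric(0)
  cur <- leaf
  t <- 0
  repeat {
    i <- match(cur, pop$name)
    breaks <- c(breaks, t)
    ne <- c(ne, pop$ne[i])
    if (is.na(pop$parent[i])) break
    t <- pop$t_end[i]
    cur <- pop$parent[i]
  }
  list(breaks = breaks, ne = ne)
}

# Small two-population clean-split model (times in generations via
# gen_time = 1).
two_pop_model <- function(t_split = 5000, ne = 10000, ne_anc = ne) {
  demographic_model(
    data.frame(name = c("A", "B", "AB"), parent = c("AB", "AB", NA),
               ne = c(ne, ne, ne_anc)),
    split_years = c(AB = t_split), gen_time = 1)
}

one_pop_model <- function(ne = 10000, name = "A") {
  demographic_model(
    data.frame(name = name, parent = NA_character_, ne = ne),
    split_years = setNames(numeric(0), character(0)), gen_time = 1)
}

# Hand-built locus set: geno is a sites x samples matrix of dosages;
# loci assigns each site to a locus.
toy_locus_set <- function(geno, loci = rep(1L, nrow(geno)),
                          n_loci = max(loci), locus_length = 1000L) {
  pos <- stats::ave(seq_along(loci), loci, FUN = seq_along) - 1L
  locus_set(geno, data.frame(locus = loci, pos = pos),
            n_loci = n_loci, locus_length = locus_length)
}

# Brute-force delete-one-block jackknife for D, independent of the
# package implementation.
brute_jackknife <- function(abba, baba) {
  use <- (abba + baba) > 0
  A <- sum(abba); B <- sum(baba)
  D <- (A - B) / (A + B)
  Dj <- vapply(which(use), function(j)
    (A - abba[j] - (B - baba[j])) / (A - abba[j] + B - baba[j]),
    numeric(1))
  g <- sum(use)
  se <- sqrt((g - 1) / g * sum((Dj - mean(Dj))^2))
  list(D = D, SE = se, Z = D / se)
}

dog_samples <- c("BOX", "BSJ", "DNG")
wolf_samples <- c("ISW", "CRW", "CHW")
canid_groups <- setNames(rep(c("dog", "wolf"), each = 3),
                         c(dog_samples, wolf_samples))
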
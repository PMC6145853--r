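#' One-way random-effects intraclass correlation
#'
#' ICC(1,1) from a one-way ANOVA of values grouped by condition:
#' `ICC = (MSB - MSW) / (MSB + (k0 - 1) * MSW)` where MSB and MSW are the
#' between- and within-group mean squares and
#' `k0 = (N - sum(k_i^2) / N) / (g - 1)` is the effective group size
#' (equal to the common group size when balanced). Here the task conditions
#' play the role of "raters" and a trait's per-profile weights the scores:
#' high ICC means the weights separate the conditions.
#'
#' @param values numeric vector (e.g. robust-trait weights); missing values
#'   are dropped with their group labels.
#' @param groups vector of condition labels, parallel to `values`.
#' @return list: `icc`, `msb`, `msw`, `k0`, `group_sizes`, `group_means`.
#' @export
icc_oneway <- function(values, groups) {
  stopifnot(length(values) == length(groups))
  keep <- !is.na(values)
  values <- values[keep]
  groups <- as.character(groups)[keep]
  sizes <- table(groups)
  if (length(sizes) < 2) stop("ICC needs >= 2 groups")
  if (any(sizes < 2)) stop("every group needs >= 2 non-missing values")
  N <- length(values); g <- length(sizes)
  gm <- tapply(values, groups, mean)
  grand <- mean(values)
  ssb <- sum(as.numeric(sizes) * (gm - grand)^2)
  ssw <- sum((values - gm[groups])^2)
  msb <- ssb / (g - 1)
  msw <- ssw / (N - g)
  if (msb == 0 && msw == 0)
    stop("all values identical; ICC undefined")
  k0 <- (N - sum(as.numeric(sizes)^2) / N) / (g - 1)
  icc <- (msb - msw) / (msb + (k0 - 1) * msw)
  list(icc = icc, msb = msb, msw = msw, k0 = k0,
       group_sizes = as.integer(sizes),
       group_means = gm)
}

#' Score robust traits for task sensitivity
#'
#' Computes the one-way ICC of each trait's weights across conditions and
#' flags traits at `icc_threshold`. A task-sensitive trait is one whose
#' expression systematically shifts with the task being performed.
#'
#' @param traits list of `robust_trait` objects (or a `decomposition`).
#' @param conditions per-profile condition labels (taken from the
#'   decomposition when one is passed).
#' @param icc_threshold flag cut on ICC (default 0.5).
#' @return data.frame sorted by ICC descending: trait id, frequency, icc,
#'   msb, msw, task_sensitive flag.
#' @export
classify_task_sensitive <- function(traits, conditions = NULL,
                                    icc_threshold = 0.5) {
  if (inherits(traits, "decomposition")) {
    conditions <- traits$condition
    traits <- traits$traits
  }
  if (inherits(traits, "robust_trait")) traits <- list(traits)
  stopifnot(length(traits) >= 1, !is.null(conditions))
  rows <- lapply(seq_along(traits), function(i) {
    t <- traits[[i]]
    icc <- icc_oneway(t$weights, conditions)
    data.frame(trait = i, frequency = t$frequency, icc = icc$icc,
               msb = icc$msb, msw = icc$msw,
               task_sensitive = icc$icc >= icc_threshold)
  })
  rep <- do.call(rbind, rows)
  rep[order(-rep$icc), ]
}
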
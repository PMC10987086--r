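#' Z-score Weber fractions within each target
#'
#' Standardises every target's participant vector to mean 0 and sample SD 1.
#' Both the clustering and the factor paths operate on these normalised
#' (and thereby centred) values.
#'
#' @param wfm A [wf_matrix] with >= 2 participants.
#' @return A `wf_matrix` of z-scored values (same shape and labels).
#' @export
zscore_targets <- function(wfm) {
  v <- wf_values(wfm)
  if (nrow(v) < 2) abort("Need >= 2 participants to z-score.")
  sds <- col_sds(v)
  if (any(sds == 0)) {
    abort(sprintf("Target(s) with zero variance cannot be z-scored: %s",
                  paste(wf_targets(wfm)[sds == 0], collapse = ", ")))
  }
  z <- scale(v)
  new_wf_matrix(z, wfm$participant_id, wf_targets(wfm), wf_condition(wfm))
}

#' Inconsistency coefficients of a dendrogram
#'
#' For each merge, compares its height with the mean and SD of the heights of
#' the merges up to `depth` levels below it (the merge itself included):
#' `(h - mean) / sd`, or 0 when fewer than two heights enter or their SD is
#' zero. Large values mark merges that join much more distant clusters than
#' those they build on.
#'
#' @param hc An [stats::hclust] object.
#' @param depth Levels of the tree included below each merge (default 3; at
#'   depth 2 the coefficient compares a merge only with its two immediate
#'   children, which makes it noisy and the resulting cut unstable).
#' @return Numeric vector, one coefficient per merge.
#' @export
inconsistency_coefficients <- function(hc, depth = 3) {
  m <- hc$merge
  h <- hc$height
  collect <- function(i, d) {
    if (d == 0L || i < 0) return(integer(0))
    c(i, collect(m[i, 1], d - 1L), collect(m[i, 2], d - 1L))
  }
  vapply(seq_len(nrow(m)), function(i) {
    s <- h[collect(i, depth)]
    if (length(s) < 2) return(0)
    sdv <- sd(s)
    if (sdv == 0) 0 else (h[i] - mean(s)) / sdv
  }, numeric(1))
}

# Leaf cluster labels after breaking every merge whose inconsistency exceeds
# the cutoff. A merge is broken if it is cut itself or sits above a cut merge;
# clusters are the maximal intact subtrees (bottom-up semantics).
clusters_from_cut <- function(m, broken) {
  n <- nrow(m)
  n_leaf <- n + 1L
  parent <- integer(n)
  leaf_parent <- integer(n_leaf)
  for (i in seq_len(n)) {
    for (j in 1:2) {
      ch <- m[i, j]
      if (ch < 0) leaf_parent[-ch] <- i else parent[ch] <- i
    }
  }
  top <- integer(n_leaf)
  for (l in seq_len(n_leaf)) {
    k <- leaf_parent[l]
    if (broken[k]) {
      top[l] <- -l
      next
    }
    while (parent[k] != 0L && !broken[parent[k]]) k <- parent[k]
    top[l] <- k
  }
  as.integer(factor(top, levels = unique(top)))
}

cut_by_inconsistency <- function(hc, inc, cutoff) {
  m <- hc$merge
  n <- nrow(m)
  cut <- inc >= cutoff
  broken <- logical(n)
  for (i in seq_len(n)) {
    broken[i] <- cut[i] ||
      (m[i, 1] > 0 && broken[m[i, 1]]) ||
      (m[i, 2] > 0 && broken[m[i, 2]])
  }
  clusters_from_cut(m, broken)
}

#' Hierarchical clustering of targets by their Weber-fraction profiles
#'
#' Clusters the targets (items) by their z-scored Weber fractions across
#' participants (features), using Euclidean distances and Ward linkage. The
#' tree is cut by the inconsistency coefficient: the cutoff defaults to the
#' maximum inconsistency in the tree, the most conservative value that still
#' splits it (merges at or above the cutoff are broken).
#'
#' @param wfm A [wf_matrix] with >= 3 targets.
#' @param depth Depth for [inconsistency_coefficients()].
#' @param cutoff Inconsistency cutoff; `NULL` (default) uses the maximum.
#' @return An object of class `channel_clusters`: list with `hclust`, the
#'   per-merge `inconsistency`, the `cutoff`, integer `assignments` (named by
#'   target, labelled in order of the lowest target they contain),
#'   `n_clusters`, and `contiguous` (are all clusters intervals of the target
#'   order?).
#' @export
hierarchical_clusters <- function(wfm, depth = 3, cutoff = NULL) {
  targets <- wf_targets(wfm)
  if (length(targets) < 3) abort("Need >= 3 targets to cluster.")
  z <- wf_values(zscore_targets(wfm))
  items <- t(z)                       # rows = targets, features = participants
  rownames(items) <- as.character(targets)
  hc <- hclust(dist(items, method = "euclidean"), method = "ward.D2")
  inc <- inconsistency_coefficients(hc, depth = depth)
  if (is.null(cutoff)) cutoff <- max(inc)
  assignments <- cut_by_inconsistency(hc, inc, cutoff)
  names(assignments) <- as.character(targets)
  structure(
    list(
      hclust = hc,
      inconsistency = inc,
      depth = depth,
      cutoff = cutoff,
      assignments = assignments,
      n_clusters = length(unique(assignments)),
      contiguous = is_contiguous(assignments, targets),
      targets = targets
    ),
    class = "channel_clusters"
  )
}

#' @export
print.channel_clusters <- function(x, ...) {
  cat(sprintf("<channel_clusters: %d clusters over %d targets (cutoff %.3f)>\n",
              x$n_clusters, length(x$targets), x$cutoff))
  for (k in sort(unique(x$assignments))) {
    cat(sprintf("  cluster %d: %s\n", k,
                paste(x$targets[x$assignments == k], collapse = ", ")))
  }
  cat(sprintf("  contiguous: %s\n", x$contiguous))
  invisible(x)
}

#' Are all clusters contiguous intervals of the target order?
#'
#' @param assignments Integer cluster labels, aligned with `targets` (or with
#'   the ascending order of their names).
#' @param targets The ordered target levels.
#' @return `TRUE` iff every cluster occupies a consecutive run of targets.
#' @export
#' @examples
#' is_contiguous(c(1, 1, 2, 2), c(8, 10, 16, 32))
#' is_contiguous(c(1, 2, 2, 1), c(8, 10, 16, 32))
is_contiguous <- function(assignments, targets) {
  if (length(assignments) != length(targets)) {
    abort("`assignments` must label every target.")
  }
  a <- assignments[order(targets)]
  all(vapply(unique(a), function(k) {
    idx <- which(a == k)
    all(diff(idx) == 1L)
  }, logical(1)))
}

#' Permutation null for cluster contiguity
#'
#' On each iteration, every participant's Weber fractions are shuffled across
#' targets, the clustering recomputed under the same cut rule, and the
#' proportion of iterations in which all clusters contain only contiguous
#' targets is returned. Contiguous solutions are rare under this null, so a
#' high observed contiguity is evidence of genuine neighbourhood structure.
#'
#' @param wfm A [wf_matrix].
#' @param n_iter Number of iterations (default 10000).
#' @param seed Integer seed.
#' @param depth Inconsistency depth (default 3).
#' @return A list: `proportion_contiguous`, `n_iter`, `n_clusters` (per
#'   iteration), `seed`.
#' @export
contiguity_null <- function(wfm, n_iter = 10000, seed = 1, depth = 3) {
  if (n_iter < 1) abort("`n_iter` must be >= 1.")
  v <- wf_values(wfm)
  targets <- wf_targets(wfm)
  n_t <- length(targets)
  res <- withr::with_seed(as.integer(seed), {
    contig <- logical(n_iter)
    nclus <- integer(n_iter)
    perm <- v
    for (it in seq_len(n_iter)) {
      for (i in seq_len(nrow(v))) perm[i, ] <- v[i, sample.int(n_t)]
      z <- scale(perm)
      hc <- hclust(dist(t(z)), method = "ward.D2")
      inc <- inconsistency_coefficients(hc, depth = depth)
      a <- cut_by_inconsistency(hc, inc, max(inc))
      contig[it] <- is_contiguous(a, targets)
      nclus[it] <- length(unique(a))
    }
    list(contig = contig, nclus = nclus)
  })
  list(
    proportion_contiguous = mean(res$contig),
    n_iter = n_iter,
    n_clusters = res$nclus,
    seed = seed
  )
}

#' Component/factor solution of the Weber-fraction correlation structure
#'
#' Principal components of the targets x targets correlation matrix of
#' z-scored Weber fractions. Components with eigenvalue > 1 are retained and
#' (for two or more) rotated, by default with the oblique promax method.
#' Loading signs are fixed so each component's largest-magnitude loading is
#' positive; components are ordered by variance explained.
#'
#' @param wfm A [wf_matrix]; needs more participants than retained components
#'   and no zero-variance target.
#' @param rotation `"promax"` (default), `"varimax"`, or `"none"`.
#' @return An object of class `component_solution`: `loadings` (targets x
#'   components matrix), `n_components`, `eigenvalues`,
#'   `variance_explained` (per retained component, as proportions),
#'   `total_variance`, `rotation`.
#' @export
factor_solution <- function(wfm, rotation = c("promax", "varimax", "none")) {
  rotation <- match.arg(rotation)
  v <- wf_values(wfm)
  targets <- wf_targets(wfm)
  sds <- col_sds(v)
  if (any(sds == 0)) {
    abort(sprintf("Target(s) with zero variance: %s",
                  paste(targets[sds == 0], collapse = ", ")))
  }
  R <- cor(v)
  eig <- eigen(R, symmetric = TRUE)
  ev <- eig$values
  k <- sum(ev > 1)
  if (k < 1) k <- 1L  # degenerate input: keep the dominant component
  if (nrow(v) <= k) abort("Need more participants than retained components.")
  L <- eig$vectors[, seq_len(k), drop = FALSE] %*%
    diag(sqrt(ev[seq_len(k)]), k, k)
  rot_applied <- "none"
  if (k >= 2 && rotation != "none") {
    rot <- tryCatch(
      if (rotation == "promax") promax(L) else varimax(L),
      error = function(e) {
        abort(sprintf("Rotation failed to converge: %s", conditionMessage(e)),
              unrotated_loadings = L)
      }
    )
    L <- unclass(rot$loadings)
    rot_applied <- rotation
  }
  # sign convention and ordering by explained variance
  for (j in seq_len(k)) {
    if (L[which.max(abs(L[, j])), j] < 0) L[, j] <- -L[, j]
  }
  ssl <- colSums(L^2)
  ord <- order(ssl, decreasing = TRUE)
  L <- L[, ord, drop = FALSE]
  dimnames(L) <- list(as.character(targets), paste0("component_", seq_len(k)))
  structure(
    list(
      loadings = L,
      n_components = k,
      eigenvalues = ev,
      variance_explained = ev[seq_len(k)] / length(ev),
      total_variance = sum(ev[seq_len(k)]) / length(ev),
      rotation = rot_applied,
      targets = targets
    ),
    class = "component_solution"
  )
}

#' @export
print.component_solution <- function(x, ...) {
  cat(sprintf("<component_solution: %d component(s), rotation %s>\n",
              x$n_components, x$rotation))
  cat(sprintf("  variance explained: %s (total %.1f%%)\n",
              paste(sprintf("%.1f%%", 100 * x$variance_explained), collapse = ", "),
              100 * x$total_variance))
  print(round(x$loadings, 3))
  invisible(x)
}

#' Tidy / summarise a component solution
#'
#' `tidy()` returns loadings in long format; `glance()` a one-row summary.
#'
#' @param x A `component_solution`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy component_solution
#' @export
tidy.component_solution <- function(x, ...) {
  tibble::as_tibble(x$loadings, rownames = "target") |>
    dplyr::mutate(target = as.numeric(.data$target)) |>
    tidyr::pivot_longer(-"target", names_to = "component", values_to = "loading")
}

#' @rdname tidy.component_solution
#' @method glance component_solution
#' @export
glance.component_solution <- function(x, ...) {
  tibble::tibble(
    n_components = x$n_components,
    total_variance = x$total_variance,
    rotation = x$rotation,
    largest_eigenvalue = x$eigenvalues[1]
  )
}

#' Log-Gaussian tuning fit to a component's loading profile
#'
#' Least-squares fit of `a * exp(-(log10(n / peak))^2 / (2 w^2))` to the
#' per-target loadings of one component, describing the component as a tuned
#' channel with a preferred numerosity (`peak`) and a width in log10 units.
#'
#' @param loadings Per-target component strengths (negative values allowed).
#' @param targets Target numerosities (>= 4 with finite loadings).
#' @return An object of class `loggaussian_fit`: `peak`, `width`,
#'   `amplitude`, `r2`, `converged`, and the fitted curve. Degenerate inputs
#'   (e.g. constant loadings) return a wide, flat fit with `r2 = 0` rather
#'   than failing.
#' @export
loggaussian_fit <- function(loadings, targets) {
  ok <- is.finite(loadings) & is.finite(targets) & targets > 0
  if (sum(ok) < 4) abort("Need >= 4 targets with finite loadings.")
  y <- loadings[ok]
  n <- targets[ok]
  w_pos <- pmax(y, 0) + 1e-9
  start <- list(
    a = max(y),
    peak = exp(sum(w_pos * log(n)) / sum(w_pos)),
    w = 0.2
  )
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ a * exp(-(log10(n / peak))^2 / (2 * w^2)),
      start = start,
      lower = c(a = -Inf, peak = min(n) / 4, w = 1e-3),
      upper = c(a = Inf, peak = max(n) * 4, w = 10),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) NULL
  )
  if (!is.null(fit)) {
    p <- coef(fit)
    pred <- p[["a"]] * exp(-(log10(n / p[["peak"]]))^2 / (2 * p[["w"]]^2))
    converged <- TRUE
  } else {
    # Nelder-Mead fallback on log-transformed scale parameters
    obj <- function(th) {
      pr <- th[1] * exp(-(log10(n / exp(th[2])))^2 / (2 * exp(th[3])^2))
      sum((y - pr)^2)
    }
    op <- optim(c(start$a, log(start$peak), log(start$w)), obj,
                method = "Nelder-Mead",
                control = list(maxit = 2000))
    p <- c(a = op$par[1], peak = exp(op$par[2]), w = exp(op$par[3]))
    pred <- p[["a"]] * exp(-(log10(n / p[["peak"]]))^2 / (2 * p[["w"]]^2))
    converged <- op$convergence == 0
  }
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot == 0) 0 else 1 - sum((y - pred)^2) / ss_tot
  structure(
    list(
      peak = unname(p[["peak"]]),
      width = unname(abs(p[["w"]])),
      amplitude = unname(p[["a"]]),
      r2 = r2,
      converged = converged,
      data = tibble::tibble(target = n, loading = y, fitted = pred)
    ),
    class = "loggaussian_fit"
  )
}

#' @export
print.loggaussian_fit <- function(x, ...) {
  cat(sprintf("<loggaussian_fit: peak %.3g, width %.3g log10 units, amplitude %.3g, R^2 %.3f>\n",
              x$peak, x$width, x$amplitude, x$r2))
  invisible(x)
}

#' @rdname loggaussian_tidiers
#' @method tidy loggaussian_fit
#' @export
tidy.loggaussian_fit <- function(x, ...) {
  tibble::tibble(
    term = c("peak", "width", "amplitude"),
    estimate = c(x$peak, x$width, x$amplitude)
  )
}

#' Tidy / summarise a log-Gaussian tuning fit
#'
#' @param x A `loggaussian_fit`.
#' @param ... Unused.
#' @return A tibble.
#' @name loggaussian_tidiers
#' @method glance loggaussian_fit
#' @export
glance.loggaussian_fit <- function(x, ...) {
  tibble::tibble(peak = x$peak, width = x$width, amplitude = x$amplitude,
                 r2 = x$r2, converged = x$converged)
}

#' Export a dendrogram
#'
#' `cluster_newick()` renders the clustering tree as a Newick string (targets
#' as leaves, merge heights as node depths, via \pkg{ape});
#' `write_cluster_result()` serialises the merge list, inconsistency
#' coefficients and assignments to JSON.
#'
#' @param clusters A `channel_clusters` object.
#' @param path Output path (for the JSON writer).
#' @return `cluster_newick()` a character scalar; `write_cluster_result()`
#'   `path`, invisibly.
#' @export
cluster_newick <- function(clusters) {
  stopifnot(inherits(clusters, "channel_clusters"))
  ape::write.tree(ape::as.phylo(clusters$hclust))
}

#' @rdname cluster_newick
#' @export
write_cluster_result <- function(clusters, path) {
  stopifnot(inherits(clusters, "channel_clusters"))
  out <- list(
    merges = apply(clusters$hclust$merge, 1, identity, simplify = FALSE),
    heights = clusters$hclust$height,
    inconsistency = clusters$inconsistency,
    cutoff = clusters$cutoff,
    assignments = as.list(clusters$assignments),
    n_clusters = clusters$n_clusters,
    contiguous = clusters$contiguous,
    newick = cluster_newick(clusters)
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
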
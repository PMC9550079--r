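## Single-threshold general mixed Yule-coalescent (GMYC) fit.
##
## On an ultrametric tree, a threshold time T (before present) separates
## between-species branching (older than T) from within-species
## coalescence (younger). Branching events are scanned from the root
## towards the present; in the interval preceding event k, with waiting
## time x_k, the total event rate is
##
##   b_k = lambda_between * n_k^p_between
##       + lambda_within * sum_j n_{j,k} * (n_{j,k} - 1)^p_within
##
## where n_k counts between-species lineages and n_{j,k} the lineages
## inside cluster j. Each event contributes log b_k - b_k x_k; the final
## interval from the last event to the present contributes the survival
## term -b_k x_k. The null model is a single branching process over all
## events (b_k = lambda * n_k^p). The likelihood-ratio test uses 3 degrees
## of freedom, the standard choice for the single-threshold model. The
## scaling exponents are fixed to 1 by default and can be optimized.

## Node heights above the present for every node (tips ~ 0), plus
## ultrametricity check (relative tolerance on root-to-tip spread).
.tree_heights <- function(tree, tol = 1e-6) {
  if (!inherits(tree, "phylo")) bc_stop("tree must be an ape 'phylo' object")
  n <- length(tree$tip.label)
  if (n < 3L) bc_stop("GMYC needs a tree with at least 3 tips")
  if (is.null(tree$edge.length)) bc_stop("tree has no branch lengths")
  if (any(tree$edge.length < 0)) bc_stop("negative branch lengths")
  depth <- ape::node.depth.edgelength(tree)   # root = 0
  tipd <- depth[seq_len(n)]
  h0 <- max(tipd)
  if (h0 <= 0) bc_stop("tree has zero height")
  if ((max(tipd) - min(tipd)) / h0 > tol)
    bc_stop("tree is not ultrametric within relative tolerance %g", tol)
  height <- h0 - depth
  height[seq_len(n)] <- 0
  height
}

## Event table: for each inter-event interval the waiting time and, per
## candidate threshold, lineage counts. Events = internal node heights
## sorted decreasing; the root is the starting condition. Returns the
## building blocks for the interval likelihood at a given threshold.
.gmyc_intervals <- function(tree, height) {
  n <- length(tree$tip.label)
  inner <- (n + 1L):(n + tree$Nnode)
  ev <- sort(height[inner], decreasing = TRUE)   # root first
  parent_h <- height[tree$edge[, 1L]]
  child_h <- height[tree$edge[, 2L]]
  list(events = ev, parent_h = parent_h, child_h = child_h,
       edge = tree$edge, n_tip = n)
}

## Clusters at threshold Tt: one cluster per edge crossing Tt, tips of the
## crossing edge's child subtree. Returns membership (tip index -> cluster)
.clusters_at <- function(tree, height, Tt) {
  n <- length(tree$tip.label)
  parent_h <- height[tree$edge[, 1L]]
  child_h <- height[tree$edge[, 2L]]
  cross <- which(parent_h > Tt & child_h <= Tt)
  member <- integer(n)
  for (k in seq_along(cross)) {
    ch <- tree$edge[cross[k], 2L]
    if (ch <= n) member[ch] <- k
    else {
      desc <- .subtree_tips(tree, ch)
      member[desc] <- k
    }
  }
  if (any(member == 0L)) {         # threshold at/above root: one cluster
    member[] <- 1L
  }
  member
}

## Tip indices under an internal node (iterative stack, no recursion cap).
.subtree_tips <- function(tree, node) {
  n <- length(tree$tip.label)
  kids <- split(tree$edge[, 2L], tree$edge[, 1L])
  stack <- node
  tips <- integer(0)
  while (length(stack)) {
    v <- stack[[length(stack)]]
    stack <- stack[-length(stack)]
    if (v <= n) tips <- c(tips, v)
    else stack <- c(stack, kids[[as.character(v)]])
  }
  tips
}

## Interval statistics at threshold Tt: per interval the waiting time x,
## A = n_between^p1 and B = sum_j n_j (n_j - 1)^p2, plus whether the
## interval ends with an event (log-term) or at the present (survival).
.interval_stats <- function(tree, height, Tt, p1 = 1, p2 = 1) {
  iv <- .gmyc_intervals(tree, height)
  ev <- iv$events
  bounds <- c(ev, 0)               # interval k: (bounds[k], bounds[k+1])
  n_int <- length(bounds) - 1L
  member <- .clusters_at(tree, height, Tt)
  C <- max(member)
  ## map every edge to the cluster its lineage belongs to (0 = between)
  edge_cluster <- integer(nrow(iv$edge))
  n <- iv$n_tip
  for (e in seq_len(nrow(iv$edge))) {
    ch <- iv$edge[e, 2L]
    tip1 <- if (ch <= n) ch else .subtree_tips(tree, ch)[1L]
    ## edge is within-cluster iff it lies entirely below the threshold
    edge_cluster[e] <- if (iv$parent_h[e] <= Tt) member[tip1] else 0L
  }
  x <- A <- B <- numeric(n_int)
  has_event <- c(rep(TRUE, n_int - 1L), FALSE)
  ## skip the first "interval" (the root event itself starts the process):
  ## interval k runs from bounds[k] down to bounds[k+1]; the event ending
  ## it is the node at bounds[k+1] (none for the last).
  for (k in seq_len(n_int)) {
    top <- bounds[k]; bot <- bounds[k + 1L]
    x[k] <- top - bot
    tmid <- (top + bot) / 2
    crossing <- iv$parent_h > tmid & iv$child_h <= tmid
    if (tmid > Tt) {
      A[k] <- sum(crossing)^p1
      B[k] <- 0
    } else {
      A[k] <- C^p1
      cl <- edge_cluster[crossing]
      nj <- tabulate(cl[cl > 0L], nbins = C)
      nj <- nj[nj >= 2L]            # singleton lineages contribute no rate
      B[k] <- if (length(nj)) sum(nj * (nj - 1)^p2) else 0
    }
  }
  list(x = x, A = A, B = B, has_event = has_event)
}

## Log-likelihood for rates lam = c(lambda_between, lambda_within) given
## interval stats; survival-only intervals contribute no log term.
.interval_loglik <- function(lam, st) {
  b <- lam[1L] * st$A + lam[2L] * st$B
  if (any(b[st$has_event] <= 0)) return(-Inf)
  sum(log(b[st$has_event])) - sum(b * st$x)
}

## Maximize over nonnegative rates. When all B are zero the within rate is
## unidentifiable and the closed-form single-rate MLE applies.
.fit_rates <- function(st) {
  E <- sum(st$has_event)
  if (all(st$B == 0)) {
    lam1 <- E / sum(st$A * st$x)
    return(list(lambda = c(lam1, 0),
                logL = .interval_loglik(c(lam1, 0), st)))
  }
  tot <- sum((st$A + st$B) * st$x)
  init <- log(rep(max(E / tot, 1e-8), 2L))
  nll <- function(lp) -.interval_loglik(exp(lp), st)
  opt <- stats::optim(init, nll, method = "Nelder-Mead",
                      control = list(maxit = 500, reltol = 1e-10))
  list(lambda = exp(opt$par), logL = -opt$value)
}

## Null model: single process over all events, b = lambda * n^p.
.fit_null <- function(tree, height, p = 1) {
  st <- .interval_stats(tree, height, Tt = -1, p1 = p, p2 = 1)
  ## Tt = -1 puts every interval above the threshold: A = lineage count
  E <- sum(st$has_event)
  lam <- E / sum(st$A * st$x)
  list(lambda = lam, logL = .interval_loglik(c(lam, 0), st))
}

#' Fit the single-threshold general mixed Yule-coalescent model
#'
#' Locates the transition point between inter-species branching and
#' intra-species coalescence on a rooted ultrametric tree by maximizing the
#' mixed Yule-coalescent likelihood over candidate thresholds (midpoints
#' between consecutive distinct node heights, plus one below the youngest
#' node), and partitions the tips into putative species at the best
#' threshold. Tips whose terminal branch crosses the threshold become
#' singleton putative species.
#'
#' @param tree a rooted ultrametric `phylo` tree with at least 3 tips.
#' @param optimize_p also optimize the scaling exponents (default `FALSE`:
#'   both fixed to 1).
#' @param tol relative ultrametricity tolerance (default 1e-6).
#' @return An object of class `gmyc`: threshold time `threshold`, rates
#'   `lambda_between` / `lambda_within`, exponents `p_between` /
#'   `p_within`, `logL_model`, `logL_null`, `lrt_pvalue` (chi-square,
#'   df 3), `partition` (a [partition()]), and the per-threshold profile
#'   in `profile`.
#' @export
gmyc_single_threshold <- function(tree, optimize_p = FALSE, tol = 1e-6) {
  height <- .tree_heights(tree, tol)
  n <- length(tree$tip.label)
  hs <- sort(unique(round(height[(n + 1L):(n + tree$Nnode)], 12L)),
             decreasing = TRUE)
  ## midpoints between distinct heights, plus the two boundary
  ## configurations: below the youngest node (every tip its own species,
  ## which reduces to the null) and above the root (one species, pure
  ## coalescence)
  cand <- if (length(hs) >= 2L)
    c(hs[1L] * 1.5, (hs[-length(hs)] + hs[-1L]) / 2, hs[length(hs)] / 2)
  else c(hs[1L] * 1.5, hs[1L] / 2)
  fit_at <- function(Tt, p1, p2) {
    st <- .interval_stats(tree, height, Tt, p1, p2)
    .fit_rates(st)
  }
  eval_threshold <- function(Tt) {
    if (!optimize_p) {
      f <- fit_at(Tt, 1, 1)
      c(f$logL, f$lambda, 1, 1)
    } else {
      obj <- function(par) {
        f <- fit_at(Tt, par[1L], par[2L])
        -f$logL
      }
      op <- stats::optim(c(1, 1), obj, method = "Nelder-Mead",
                         control = list(maxit = 200, reltol = 1e-8))
      f <- fit_at(Tt, op$par[1L], op$par[2L])
      c(f$logL, f$lambda, op$par)
    }
  }
  prof <- t(vapply(cand, eval_threshold, numeric(5)))
  colnames(prof) <- c("logL", "lambda_between", "lambda_within",
                      "p_between", "p_within")
  best <- which.max(prof[, "logL"])
  if (!is.finite(prof[best, "logL"]))
    bc_stop("GMYC optimization failed to converge at every threshold")
  null <- .fit_null(tree, height, p = if (optimize_p) prof[best, "p_between"] else 1)
  logL_model <- max(prof[best, "logL"], null$logL)
  lrt <- max(0, 2 * (logL_model - null$logL))
  member <- .clusters_at(tree, height, cand[best])
  assign <- stats::setNames(sprintf("G%03d", member), tree$tip.label)
  structure(list(threshold = min(cand[best], max(height)),
                 lambda_between = unname(prof[best, "lambda_between"]),
                 lambda_within = unname(prof[best, "lambda_within"]),
                 p_between = unname(prof[best, "p_between"]),
                 p_within = unname(prof[best, "p_within"]),
                 logL_model = logL_model,
                 logL_null = null$logL,
                 lrt = lrt,
                 lrt_pvalue = stats::pchisq(lrt, df = 3, lower.tail = FALSE),
                 partition = partition(assign, "gmyc"),
                 profile = data.frame(threshold = cand, prof),
                 n_tip = n),
            class = "gmyc")
}

#' @export
print.gmyc <- function(x, ...) {
  cat("Single-threshold GMYC fit\n")
  cat(sprintf("  tips: %d   clusters: %d\n", x$n_tip, n_groups(x$partition)))
  cat(sprintf("  threshold time: %.6g before present\n", x$threshold))
  cat(sprintf("  logL model: %.4f   logL null: %.4f   LRT p = %.4g\n",
              x$logL_model, x$logL_null, x$lrt_pvalue))
  invisible(x)
}

#' @export
summary.gmyc <- function(object, ...) {
  print(object)
  cat(sprintf("  lambda_between: %.4g (exponent %.3g)\n",
              object$lambda_between, object$p_between))
  cat(sprintf("  lambda_within:  %.4g (exponent %.3g)\n",
              object$lambda_within, object$p_within))
  sizes <- table(object$partition$assignment)
  cat(sprintf("  cluster sizes: %s\n",
              paste(sort(as.integer(sizes), decreasing = TRUE), collapse = " ")))
  invisible(object)
}

#' @export
logLik.gmyc <- function(object, ...) {
  structure(object$logL_model, df = 3, class = "logLik")
}

#' @export
plot.gmyc <- function(x, ...) {
  graphics::plot(x$profile$threshold, x$profile$logL, type = "b",
                 xlab = "threshold time before present",
                 ylab = "log-likelihood", ...)
  graphics::abline(v = x$threshold, lty = 2)
  invisible(x)
}

#' GMYC fit summary as JSON
#'
#' @param x a `gmyc` fit.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gmyc_json <- function(x, path) {
  jsonlite::write_json(list(threshold = x$threshold,
                            lambda_between = x$lambda_between,
                            lambda_within = x$lambda_within,
                            p_between = x$p_between,
                            p_within = x$p_within,
                            logL_model = x$logL_model,
                            logL_null = x$logL_null,
                            lrt_pvalue = x$lrt_pvalue,
                            n_clusters = n_groups(x$partition)),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
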
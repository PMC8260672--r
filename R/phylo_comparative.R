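# Maximum-likelihood ancestral state reconstruction of continuous count
# traits under Brownian motion.
#
# Under Brownian motion the tip values are multivariate normal with
# covariance sigma2 * C, where C[i, j] is the branch length shared on the
# paths from the root to tips i and j. The ML estimate of the state at an
# internal node equals the generalized-least-squares root-state estimate of
# the tree re-rooted at that node:
#
#   a_hat(v) = (1' C_v^-1 1)^-1  1' C_v^-1 x
#
# with C_v the Brownian covariance under rooting at v. Rather than literally
# re-rooting, C_v is computed from unrooted path lengths:
# C_v[i, j] = (d(v, i) + d(v, j) - d(i, j)) / 2, which equals the shared
# root-to-MRCA depth under rooting at v. Joint ML over all internal states
# gives the same estimates (the estimates minimize the edge-wise weighted sum
# of squares sum (x_child - x_parent)^2 / length), which is what the
# numerical oracle in the test suite checks.

#' Brownian-motion covariance matrix of the tips
#'
#' `C[i, j]` is the total branch length from `root_node` to the most recent
#' common ancestor of tips `i` and `j` (their shared path length), computed
#' from pairwise node distances as
#' `(d(root, i) + d(root, j) - d(i, j)) / 2`. Works for any node degree.
#'
#' @param tree an [ape] `phylo` tree with branch lengths.
#' @param root_node node number to treat as the root (default: the tree's
#'   root, `Ntip + 1`).
#' @return symmetric tip-by-tip matrix with tip labels as dimnames.
#' @export
bm_covariance <- function(tree, root_node = NULL) {
  validate_tree(tree)
  ntip <- length(tree$tip.label)
  if (is.null(root_node)) root_node <- ntip + 1L
  D <- ape::dist.nodes(tree)
  if (any(!is.finite(D))) stopf("ill-formed tree: non-finite node distances")
  tips <- seq_len(ntip)
  C <- 0.5 * (outer(D[root_node, tips], D[root_node, tips], `+`) -
                D[tips, tips])
  # guard tiny negative round-off on the diagonal of shared paths
  C[abs(C) < 1e-12] <- 0
  dimnames(C) <- list(tree$tip.label, tree$tip.label)
  C
}

#' ML ancestral state reconstruction of a continuous trait
#'
#' Estimates the ancestral state at every internal node by the re-rooting
#' GLS formula (see the package vignette), together with the ML Brownian
#' rate `sigma2_hat` (residual quadratic form divided by the number of tips)
#' and, per node, the conditional GLS variance
#' `sigma2_hat / (1' C_v^-1 1)` under that node's rooting.
#'
#' Zero-length internal branches are collapsed to multifurcations before the
#' analysis; zero-length terminal branches make the covariance singular and
#' raise an error unless `epsilon` supplies a minimum terminal branch length.
#'
#' @param tree an [ape] `phylo` tree.
#' @param trait named numeric vector covering every tip exactly once
#'   (receptor counts are treated as continuous).
#' @param epsilon optional minimum terminal branch length substituted for
#'   zero-length terminal branches.
#' @return object of class `asr_result`: list with `estimates` and
#'   `variances` (named by internal node number), `sigma2_hat`, `root_state`
#'   and `tree` (as analysed).
#' @export
asr_ml <- function(tree, trait, epsilon = NULL) {
  validate_tree(tree)
  ntip <- length(tree$tip.label)
  if (ntip < 2L) stopf("tree must have at least 2 tips")
  miss <- setdiff(tree$tip.label, names(trait))
  extra <- setdiff(names(trait), tree$tip.label)
  if (length(miss) > 0L)
    stopf("trait missing tip(s): %s", paste(miss, collapse = ", "))
  if (length(extra) > 0L)
    stopf("trait has value(s) for unknown tip(s): %s",
          paste(extra, collapse = ", "))
  if (anyDuplicated(names(trait))) stopf("duplicate names in trait")

  terminal <- tree$edge[, 2] <= ntip
  if (any(tree$edge.length[terminal] == 0)) {
    if (is.null(epsilon))
      stopf(paste("zero-length terminal branch makes the Brownian covariance",
                  "singular; supply `epsilon` to impose a minimum terminal",
                  "branch length"))
    tree$edge.length[terminal & tree$edge.length == 0] <- epsilon
  }
  if (any(tree$edge.length[!terminal] == 0))
    tree <- ape::di2multi(tree, tol = 1e-12)

  x <- trait[tree$tip.label]
  ntip <- length(tree$tip.label)
  nodes <- seq.int(ntip + 1L, ntip + tree$Nnode)
  D <- ape::dist.nodes(tree)
  tips <- seq_len(ntip)

  gls_at <- function(v) {
    C <- 0.5 * (outer(D[v, tips], D[v, tips], `+`) - D[tips, tips])
    Cinv_x <- solve(C, cbind(x, 1))
    w <- sum(Cinv_x[, 2])
    a <- sum(Cinv_x[, 1]) / w
    list(a = a, inv_info = 1 / w, C = C)
  }

  root <- ntip + 1L
  root_fit <- gls_at(root)
  r <- x - root_fit$a
  sigma2_hat <- as.numeric(crossprod(r, solve(root_fit$C, r))) / ntip
  if (sigma2_hat < 0) sigma2_hat <- 0   # round-off at constant traits

  est <- vars <- numeric(length(nodes))
  for (i in seq_along(nodes)) {
    f <- if (nodes[i] == root) root_fit else gls_at(nodes[i])
    est[i] <- f$a
    vars[i] <- sigma2_hat * f$inv_info
  }
  names(est) <- names(vars) <- as.character(nodes)
  structure(list(estimates = est, variances = pmax(vars, 0),
                 sigma2_hat = sigma2_hat,
                 root_state = est[[as.character(root)]], tree = tree),
            class = "asr_result")
}

#' @export
print.asr_result <- function(x, ...) {
  cat(sprintf("<asr_result> %d internal node(s); sigma2_hat = %.4g; root = %.4g\n",
              length(x$estimates), x$sigma2_hat, x$root_state))
  invisible(x)
}

#' Batch ancestral state reconstruction over several traits
#'
#' @param tree an [ape] `phylo` tree.
#' @param traits named list of trait vectors (e.g. the four receptor type
#'   totals); all must cover the same tip set (error naming offenders
#'   otherwise).
#' @param epsilon passed to [asr_ml()].
#' @return named list of `asr_result`, in the order of `traits`.
#' @export
asr_batch <- function(tree, traits, epsilon = NULL) {
  stopifnot(is.list(traits), length(traits) > 0L)
  ref <- sort(names(traits[[1]]))
  for (nm in names(traits)) {
    if (!identical(sort(names(traits[[nm]])), ref))
      stopf("trait '%s' has a different tip set than trait '%s'",
            nm, names(traits)[1])
  }
  lapply(traits, function(tr) asr_ml(tree, tr, epsilon = epsilon))
}

#' Flatten batch ASR results into a table
#'
#' @param results named list from [asr_batch()].
#' @return `data.frame` with `trait`, `node_id`, `estimate`, `variance`,
#'   `sigma2_hat`.
#' @export
asr_table <- function(results) {
  do.call(rbind, lapply(names(results), function(nm) {
    r <- results[[nm]]
    data.frame(trait = nm, node_id = names(r$estimates),
               estimate = unname(r$estimates),
               variance = unname(r$variances),
               sigma2_hat = r$sigma2_hat, stringsAsFactors = FALSE)
  }))
}
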
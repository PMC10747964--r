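#' Pedigree kinship matrix
#'
#' Computes the kinship coefficient phi for every pair by the standard
#' recursion over a topologically sorted pedigree: founders have
#' `phi(i,i) = 1/2` and `phi(i,j) = 0`;
#' `phi(i,i) = (1 + phi(sire_i, dam_i)) / 2`; and for j processed before i,
#' `phi(i,j) = (phi(sire_i, j) + phi(dam_i, j)) / 2`.  An individual with a
#' single recorded parent is treated as if the missing parent were an
#' unrelated founder (contribution 0), the usual convention for open
#' registry pedigrees.  Twice this matrix is the numerator relationship
#' matrix, so the result is symmetric positive semidefinite with diagonal in
#' [0.5, 1].
#'
#' @param pedigree data.frame with columns `id`, `sire`, `dam` (`NA` or
#'   absent id = founder).
#' @return symmetric matrix of kinship coefficients, dimnames = ids.
#' @export
kinship_matrix <- function(pedigree) {
  ped <- as.data.frame(pedigree)
  n <- nrow(ped)
  idx <- seq_len(n); names(idx) <- ped$id
  par_idx <- function(col) {
    p <- match(ped[[col]], ped$id)   # NA for founders/unknown parents
    p
  }
  si <- par_idx("sire"); di <- par_idx("dam")
  ord <- topo_order(si, di, ped$id)
  K <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  placed <- integer(0)
  for (i in ord) {
    s <- si[i]; d <- di[i]
    if (length(placed)) {
      row <- numeric(length(placed))
      if (!is.na(s)) row <- row + K[s, placed]
      if (!is.na(d)) row <- row + K[d, placed]
      K[i, placed] <- K[placed, i] <- row / 2
    }
    K[i, i] <- 0.5 * (1 + if (!is.na(s) && !is.na(d)) K[s, d] else 0)
    placed <- c(placed, i)
  }
  K
}

# Kahn topological sort; errors on cycles.
topo_order <- function(si, di, ids) {
  n <- length(ids)
  indeg <- (!is.na(si)) + (!is.na(di))
  children <- vector("list", n)
  for (i in seq_len(n)) {
    for (p in c(si[i], di[i])) if (!is.na(p))
      children[[p]] <- c(children[[p]], i)
  }
  queue <- which(indeg == 0L)
  ord <- integer(0)
  while (length(queue)) {
    i <- queue[1]; queue <- queue[-1]
    ord <- c(ord, i)
    for (ch in children[[i]]) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(ord) != n)
    stop("input error: pedigree contains a cycle involving '",
         ids[setdiff(seq_len(n), ord)][1], "'")
  ord
}

#' Count case descendants of a pedigree ancestor
#'
#' Number of case-flagged individuals whose ancestor closure (transitive
#' sire/dam closure) contains the given ancestor.  The ancestor itself is not
#' counted.
#'
#' @param pedigree data.frame with `id`, `sire`, `dam`.
#' @param ancestor id of the putative common ancestor.
#' @param cases character vector of case ids, or a logical vector aligned
#'   with the pedigree rows, or a phenotype table with `status == "case"`.
#' @return integer count.
#' @export
common_ancestor_cases <- function(pedigree, ancestor, cases) {
  ped <- as.data.frame(pedigree)
  if (!(ancestor %in% ped$id)) stop("input error: unknown id '", ancestor, "'")
  case_ids <- if (is.data.frame(cases)) cases$sample_id[cases$status %in% "case"]
              else if (is.logical(cases)) ped$id[cases]
              else as.character(cases)
  n <- nrow(ped)
  si <- match(ped$sire, ped$id); di <- match(ped$dam, ped$id)
  children <- vector("list", n)
  for (i in seq_len(n))
    for (p in c(si[i], di[i])) if (!is.na(p))
      children[[p]] <- c(children[[p]], i)
  # BFS over descendants
  start <- match(ancestor, ped$id)
  seen <- logical(n)
  queue <- children[[start]]
  while (length(queue)) {
    i <- queue[[1]]; queue <- queue[-1]
    if (!seen[i]) {
      seen[i] <- TRUE
      queue <- c(queue, children[[i]])
    }
  }
  sum(ped$id[seen] %in% case_ids)
}

#' Convert a kinship matrix to a distance matrix
#'
#' `d = max(phi) - phi` with a zeroed diagonal, suitable as input to
#' [mutual_knn_network()].
#' @param K kinship matrix.
#' @export
kinship_to_distance <- function(K) {
  D <- max(K) - K
  diag(D) <- 0
  D
}
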
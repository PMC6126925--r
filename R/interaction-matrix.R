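#' Reciprocal interaction matrices
#'
#' An `interaction_matrix` holds the pairwise survival probabilities
#' \eqn{I_{\alpha\beta}} of the live strains of a community: `I[a, b]` is the
#' probability that an individual of strain `a` survives a competitive
#' encounter with an individual of strain `b`.  The matrix is *reciprocal*
#' (\eqn{I_{\alpha\beta} + I_{\beta\alpha} = 1} for every pair) with a
#' constant diagonal of 0.5.  Row \eqn{\alpha} is the *interaction trait* of
#' strain \eqn{\alpha}: its behaviour towards every member of the community.
#'
#' Strains are addressed by stable integer handles that are never reused;
#' rows/columns are labelled with the handle.  The matrix grows by one
#' row/column per established mutant ([add_mutant()]) and shrinks when a
#' strain goes extinct ([remove_strain()]).
#'
#' Reciprocity is maintained *exactly* in floating point: a mutant's row is
#' written first (clipped to \eqn{[0,1]}) and the corresponding column is
#' stored as `1 -` the row, so the pair sum is exactly 1 by construction.
#'
#' @param m numeric matrix of survival probabilities (reciprocal, diagonal
#'   0.5) used to seed the object; handles are taken from its rownames or
#'   assigned `0..n-1`.
#' @return An object of class `interaction_matrix`.
#' @seealso [create_founder()], [add_mutant()], [remove_strain()],
#'   [competitive_ability()], [reciprocity_residual()]
#' @export
interaction_matrix <- function(m) {
  stopifnot(is.matrix(m), nrow(m) == ncol(m))
  n <- nrow(m)
  if (n > 0) {
    if (any(m < 0 | m > 1)) stop("entries must lie in [0, 1]")
    if (any(abs(diag(m) - 0.5) > 0)) stop("diagonal entries must equal 0.5")
  }
  h <- if (!is.null(rownames(m))) as.integer(rownames(m)) else seq_len(n) - 1L
  dimnames(m) <- list(as.character(h), as.character(h))
  structure(
    list(entries = m, handles = h, next_handle = if (n) max(h) + 1L else 0L),
    class = "interaction_matrix")
}

#' Found a community with a single strain
#'
#' The founder matrix is 1x1 with the conventional self-survival entry 0.5;
#' its competitive ability is defined as 0 while it is alone.
#'
#' @return An `interaction_matrix` with one strain (handle 0).
#' @export
create_founder <- function() {
  interaction_matrix(matrix(0.5, 1, 1, dimnames = list("0", "0")))
}

#' Number of live strains
#' @param im an `interaction_matrix`.
#' @return Integer count of live strains (the matrix dimension).
#' @export
n_strains <- function(im) length(im$handles)

.im_index <- function(im, handle) {
  i <- match(handle, im$handles)
  if (is.na(i))
    stop("unknown or retired strain handle: ", handle, call. = FALSE)
  i
}

#' Add a mutant strain
#'
#' The mutant inherits its parent's interaction trait with independent
#' zero-centred Gaussian perturbations of width `m` on every entry
#' (\eqn{I_{\alpha'\beta} = I_{\alpha\beta} + \eta_\beta}), clipped to
#' \eqn{[0,1]}.  The new column is the exact complement of the new row and
#' the mutant's self-entry is 0.5.  Parent entries are unchanged.
#'
#' @param im an `interaction_matrix`.
#' @param parent handle of the (live) parent strain.
#' @param m mutation width: standard deviation of the per-entry noise
#'   (dimensionless probability units, > 0).
#' @return The updated `interaction_matrix`; the new strain's handle is in
#'   `attr(, "new_handle")`.
#' @export
add_mutant <- function(im, parent, m) {
  stopifnot(is.numeric(m), m > 0)
  i <- .im_index(im, parent)
  n <- n_strains(im)
  row <- pmin(pmax(im$entries[i, ] + stats::rnorm(n, 0, m), 0), 1)
  h <- im$next_handle
  e <- rbind(cbind(im$entries, 1 - row, deparse.level = 0),
             c(row, 0.5), deparse.level = 0)
  lab <- c(as.character(im$handles), as.character(h))
  dimnames(e) <- list(lab, lab)
  out <- structure(
    list(entries = e, handles = c(im$handles, h), next_handle = h + 1L),
    class = "interaction_matrix")
  attr(out, "new_handle") <- h
  out
}

#' Remove an extinct strain
#'
#' Deletes the strain's row and column; all other pairwise entries are
#' unchanged and the handle is retired (never reused).
#'
#' @inheritParams add_mutant
#' @param handle handle of the (live) strain to remove.
#' @return The updated `interaction_matrix`.
#' @export
remove_strain <- function(im, handle) {
  i <- .im_index(im, handle)
  structure(
    list(entries = im$entries[-i, -i, drop = FALSE],
         handles = im$handles[-i],
         next_handle = im$next_handle),
    class = "interaction_matrix")
}

#' Competitive ability of a strain
#'
#' The mean of a strain's off-diagonal interactions,
#' \eqn{C(T_\alpha) = \frac{1}{N_{st}-1}\sum_{\beta\neq\alpha} I_{\alpha\beta}},
#' i.e. its average survival probability against the rest of the community.
#' Defined as 0 for a community of one strain.
#'
#' @inheritParams remove_strain
#' @return Competitive ability in \eqn{[0, 1]}.
#' @export
competitive_ability <- function(im, handle) {
  i <- .im_index(im, handle)
  n <- n_strains(im)
  if (n == 1) return(0)
  sum(im$entries[i, -i]) / (n - 1)
}

#' Worst-case reciprocity violation
#'
#' Audit helper: the maximum of \eqn{|I_{\alpha\beta} + I_{\beta\alpha} - 1|}
#' over all strain pairs.  Matrices built through [create_founder()],
#' [add_mutant()] and [remove_strain()] return exactly 0.
#'
#' @inheritParams add_mutant
#' @return Non-negative scalar; 0 for fewer than two strains.
#' @export
reciprocity_residual <- function(im) {
  n <- n_strains(im)
  if (n < 2) return(0)
  e <- im$entries
  s <- abs(e + t(e) - 1)
  diag(s) <- 0
  max(s)
}

#' @export
print.interaction_matrix <- function(x, ...) {
  cat("Interaction matrix:", n_strains(x), "live strain(s)\n")
  if (n_strains(x) <= 8) print(round(x$entries, 4)) else
    cat("  (entries suppressed; access via $entries)\n")
  invisible(x)
}

#' Write / read an interaction-matrix snapshot as TSV
#'
#' Plain-text snapshot with strain handles as first row and column and cells
#' written with 12 significant digits; the round trip is lossless to the
#' written precision.
#'
#' @inheritParams add_mutant
#' @param path file path.
#' @return `write_matrix_snapshot()` returns `path` invisibly;
#'   `read_matrix_snapshot()` returns an `interaction_matrix`.
#' @export
write_matrix_snapshot <- function(im, path) {
  e <- signif(im$entries, 12)
  utils::write.table(e, path, sep = "\t", quote = FALSE,
                     row.names = TRUE, col.names = NA)
  invisible(path)
}

#' @rdname write_matrix_snapshot
#' @export
read_matrix_snapshot <- function(path) {
  m <- as.matrix(utils::read.table(path, sep = "\t", header = TRUE,
                                   row.names = 1, check.names = FALSE))
  # snapshots are reciprocal to written precision; restore exactness
  m[lower.tri(m)] <- 1 - t(m)[lower.tri(m)]
  diag(m) <- 0.5
  interaction_matrix(m)
}
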
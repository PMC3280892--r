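#' Locate mean-field equilibria
#'
#' Damped Newton iteration from a grid of starting points over the state
#' space (activities in `[0,1]`, `q` in `(0,1]`), merging duplicates at
#' tolerance `1e-8`.  The phase-diagram region of interest can hold one to
#' three equilibria.
#'
#' @param spec A [network_spec()] or [depression_spec()].
#' @param n_starts Starts per dimension (default 5).
#' @param tol Newton convergence tolerance on `|rhs|`.
#' @return A tibble with one row per equilibrium: state columns, the
#'   leading eigenvalue fields `re_lambda`, `im_lambda`, and a logical
#'   `stable`.
#' @export
find_fixed_points <- function(spec, n_starts = 5, tol = 1e-12) {
  d <- spec_dim(spec)
  grid <- seq(0.05, 0.95, length.out = n_starts)
  starts <- as.matrix(expand.grid(rep(list(grid), d)))
  sols <- list()
  for (i in seq_len(nrow(starts))) {
    x <- starts[i, ]
    ok <- FALSE
    for (it in 1:100) {
      f <- meanfield_rhs(x, spec)
      if (max(abs(f)) < tol) { ok <- TRUE; break }
      J <- jacobian_matrix(x, spec)
      step <- tryCatch(solve(J, -f), error = function(e) NULL)
      if (is.null(step)) break
      lam <- 1
      fn0 <- sum(f^2)
      repeat {
        xn <- x + lam * step
        if (sum(meanfield_rhs(xn, spec)^2) < fn0 || lam < 1e-4) break
        lam <- lam / 2
      }
      x <- xn
    }
    if (ok && all(is.finite(x))) sols[[length(sols) + 1]] <- x
  }
  if (length(sols) == 0) {
    return(tibble::tibble())
  }
  sols <- do.call(rbind, sols)
  keep <- !duplicated(round(sols / 1e-8) * 1e-8)
  # merge near-duplicates pairwise
  sols <- sols[keep, , drop = FALSE]
  if (nrow(sols) > 1) {
    dup <- rep(FALSE, nrow(sols))
    for (i in seq_len(nrow(sols) - 1)) {
      if (dup[i]) next
      for (j in seq((i + 1), nrow(sols))) {
        if (max(abs(sols[i, ] - sols[j, ])) < 1e-8) dup[j] <- TRUE
      }
    }
    sols <- sols[!dup, , drop = FALSE]
  }
  eig <- t(apply(sols, 1, function(x) {
    lam <- eigen(jacobian_matrix(x, spec), only.values = TRUE)$values
    lead <- lam[which.max(Re(lam))]
    c(Re(lead), Im(lead))
  }))
  out <- tibble::as_tibble(as.data.frame(sols))
  names(out) <- spec_state_names(spec)
  out$re_lambda <- eig[, 1]
  out$im_lambda <- abs(eig[, 2])
  out$stable <- out$re_lambda < 0
  out
}
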
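# Dense two-phase primal simplex with Bland's anti-cycling rule.
#
# Solves  max/min c'x  s.t.  A1 x <= b1, A2 x >= b2, A3 x = b3, x >= 0, with
# b1, b2, b3 >= 0 (callers arrange signs). Small dense problems only; Bland's
# rule guarantees termination, full-tableau pivoting keeps the code auditable.

lp_pivot <- function(Tb, basis, cvec, tol = 1e-9, max_iter = 10000L) {
  m <- nrow(Tb); n <- ncol(Tb) - 1L
  for (iter in seq_len(max_iter)) {
    cb <- cvec[basis]
    red <- cvec - as.numeric(cb %*% Tb[, seq_len(n), drop = FALSE])
    red[basis] <- 0
    enter <- which(red > tol)
    if (!length(enter)) return(list(status = "optimal", Tb = Tb, basis = basis))
    enter <- enter[1]                       # Bland: smallest entering index
    col <- Tb[, enter]
    pos <- which(col > tol)
    if (!length(pos)) return(list(status = "unbounded", Tb = Tb, basis = basis))
    ratios <- Tb[pos, n + 1L] / col[pos]
    rmin <- min(ratios)
    cand <- pos[ratios <= rmin + tol * max(1, abs(rmin))]
    leave <- cand[which.min(basis[cand])]   # Bland: smallest leaving basic var
    piv <- Tb[leave, enter]
    Tb[leave, ] <- Tb[leave, ] / piv
    other <- setdiff(seq_len(m), leave)
    Tb[other, ] <- Tb[other, ] - outer(Tb[other, enter], Tb[leave, ])
    basis[leave] <- enter
  }
  list(status = "maxiter", Tb = Tb, basis = basis)
}

#' Solve a small dense linear program
#'
#' Two-phase primal simplex over `x >= 0` with `A1 x <= b1`, `A2 x >= b2`,
#' `A3 x = b3`, all right-hand sides non-negative. Used as the flux-balance
#' LP engine; written for auditability on toy-scale problems, not for sparse
#' genome-scale models.
#'
#' @param cvec objective coefficients.
#' @param A1,b1 less-than constraints (may be `NULL`).
#' @param A2,b2 greater-than constraints (may be `NULL`).
#' @param A3,b3 equality constraints (may be `NULL`).
#' @param maximize logical.
#' @return list: `status` (`"optimal"`, `"infeasible"`, `"unbounded"`,
#'   `"maxiter"`), `x` (solution on the original variables), `value`.
#' @export
solve_lp <- function(cvec, A1 = NULL, b1 = NULL, A2 = NULL, b2 = NULL,
                     A3 = NULL, b3 = NULL, maximize = TRUE) {
  n <- length(cvec)
  if (is.null(A1)) { A1 <- matrix(0, 0, n); b1 <- numeric(0) }
  if (is.null(A2)) { A2 <- matrix(0, 0, n); b2 <- numeric(0) }
  if (is.null(A3)) { A3 <- matrix(0, 0, n); b3 <- numeric(0) }
  stopifnot(all(b1 >= 0), all(b2 >= 0), all(b3 >= 0))
  m1 <- nrow(A1); m2 <- nrow(A2); m3 <- nrow(A3)
  m <- m1 + m2 + m3
  na <- m2 + m3                              # artificial count

  # columns: x (n) | slacks (m1) | surpluses (m2) | artificials (m2 + m3)
  M <- rbind(
    cbind(A1, diag(nrow = m1), matrix(0, m1, m2), matrix(0, m1, na)),
    cbind(A2, matrix(0, m2, m1), -diag(nrow = m2),
          diag(nrow = m2), matrix(0, m2, m3)),
    cbind(A3, matrix(0, m3, m1), matrix(0, m3, m2),
          matrix(0, m3, m2), diag(nrow = m3)))
  rhs <- c(b1, b2, b3)
  nsx <- n + m1 + m2                         # structural + slack/surplus cols
  basis <- c(n + seq_len(m1), nsx + seq_len(na))
  Tb <- cbind(M, rhs)

  if (na > 0) {                              # phase 1: drive artificials to 0
    c1 <- c(rep(0, nsx), rep(-1, na))
    ph1 <- lp_pivot(Tb, basis, c1)
    if (ph1$status != "optimal") return(list(status = "infeasible"))
    val1 <- sum(c1[ph1$basis] * ph1$Tb[, ncol(ph1$Tb)])
    if (val1 < -1e-7) return(list(status = "infeasible"))
    Tb <- ph1$Tb; basis <- ph1$basis
    art <- nsx + seq_len(na)
    for (i in which(basis %in% art)) {       # pivot out degenerate artificials
      row <- Tb[i, seq_len(nsx)]
      j <- which(abs(row) > 1e-9)
      if (length(j)) {
        piv <- Tb[i, j[1]]
        Tb[i, ] <- Tb[i, ] / piv
        other <- setdiff(seq_len(nrow(Tb)), i)
        Tb[other, ] <- Tb[other, ] - outer(Tb[other, j[1]], Tb[i, ])
        basis[i] <- j[1]
      }
    }
    keep_rows <- !(basis %in% art)           # redundant rows
    Tb <- Tb[keep_rows, , drop = FALSE]
    basis <- basis[keep_rows]
    Tb <- Tb[, c(seq_len(nsx), ncol(Tb)), drop = FALSE]
  }

  c2 <- c(if (maximize) cvec else -cvec, rep(0, m1 + m2))
  ph2 <- lp_pivot(Tb, basis, c2)
  if (ph2$status != "optimal") return(list(status = ph2$status))
  x_full <- numeric(nsx)
  x_full[ph2$basis] <- ph2$Tb[, ncol(ph2$Tb)]
  x <- x_full[seq_len(n)]
  list(status = "optimal", x = x, value = sum(cvec * x))
}
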
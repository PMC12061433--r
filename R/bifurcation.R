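#' Saddle-node bifurcation geometry of the apical compartment
#'
#' With the recovery variable treated as quasi-static, the apical
#' compartment's voltage nullcline is `u = l (v - v_r) - g f(v) - I` and
#' the recovery nullcline `u = b (v - v_r)`. Saddle-node bifurcations occur
#' where the nullclines intersect tangentially: `f'(v) = (l - b) / g`. For
#' the logistic nonlinearity `f' = f (1 - f) / 6`, so the tangency voltages
#' solve `f (1 - f) = 6 (l - b) / g` in closed form, and the bifurcation
#' currents follow from `I = (l - b)(v* - v_r) - g f(v*)`. The first
#' bifurcation current `I_B1` (where the stable plateau state is born)
#' corresponds to the upper voltage root, the second (`I_B2`, where the
#' resting state vanishes) to the lower root, and `I_B1 < I_B2`.
#'
#' @param p An [apical_params()] set.
#' @return A list of class `bifurcation_result` with `v_star` (sorted
#'   increasing, mV), `I_B1`, `I_B2` (pA), or with `exists = FALSE` when
#'   the tangency condition has no solution.
#' @export
bifurcation_points <- function(p = apical_params()) {
  rhs <- 6 * (p$l - p$b) / p$g
  if (rhs >= 0.25 || rhs <= 0) {
    return(structure(list(exists = FALSE, v_star = numeric(0),
                          I_B1 = NA_real_, I_B2 = NA_real_),
                     class = "bifurcation_result"))
  }
  # f (1 - f) = rhs -> two roots of the logistic activation
  f_roots <- c((1 - sqrt(1 - 4 * rhs)) / 2, (1 + sqrt(1 - 4 * rhs)) / 2)
  v_star <- -38 + 6 * log(f_roots / (1 - f_roots)) # inverse logistic
  I_at <- (p$l - p$b) * (v_star - p$v_r) - p$g * f_roots
  structure(list(exists = TRUE,
                 v_star = v_star,                 # increasing: lower, upper
                 I_B1 = I_at[2],                  # upper voltage root
                 I_B2 = I_at[1]),                 # lower voltage root
            class = "bifurcation_result")
}

#' @export
print.bifurcation_result <- function(x, ...) {
  if (!x$exists) {
    cat("<bifurcation_result> no saddle-node (tangency condition unmet)\n")
  } else {
    cat(sprintf("<bifurcation_result> v* = %.4f, %.4f mV; I_B1 = %.3f pA; I_B2 = %.3f pA\n",
                x$v_star[1], x$v_star[2], x$I_B1, x$I_B2))
  }
  invisible(x)
}

#' Signed distance to the first bifurcation
#'
#' `I - I_B1` in pA: positive values place the apical compartment above
#' the saddle-node at which the calcium plateau state exists.
#'
#' @param apical_input_current Apical input current (pA; every term of the
#'   apical equation except the recovery variable).
#' @param I_B1 First bifurcation current (pA), from [bifurcation_points()].
#' @return Signed distance (pA).
#' @export
distance_to_b1 <- function(apical_input_current,
                           I_B1 = bifurcation_points()$I_B1) {
  apical_input_current - I_B1
}
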
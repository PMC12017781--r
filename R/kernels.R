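# Reproducing kernels and null-space basis for the time x group SSANOVA
# decomposition on the unit interval.
#
# The smooth terms live in the cubic-spline RKHS on [0,1] generated by
#   K(s,t) = k2(s) k2(t) - k4(|s - t|),
# where k1, k2, k4 are scaled Bernoulli polynomials.  The group factor enters
# through a +-1/2 contrast; the penalized time x group interaction uses the
# tensor kernel K(s,t) * c(g) * c(g').  The unpenalized (null-space) basis is
# {1, k1(t), c(g), k1(t) c(g)}.

#' Scaled Bernoulli polynomials
#'
#' Building blocks of the cubic-spline reproducing kernel on \eqn{[0,1]}:
#' \eqn{k_1(x) = x - 1/2}, \eqn{k_2(x) = (k_1(x)^2 - 1/12)/2},
#' \eqn{k_4(x) = (k_1(x)^4 - k_1(x)^2/2 + 7/240)/24}.
#'
#' @param x numeric vector in \eqn{[0,1]}.
#' @return numeric vector of polynomial values.
#' @keywords internal
#' @name bernoulli-polys
NULL

#' @rdname bernoulli-polys
#' @export
k1 <- function(x) x - 0.5

#' @rdname bernoulli-polys
#' @export
k2 <- function(x) {
  h <- x - 0.5
  (h * h - 1 / 12) / 2
}

#' @rdname bernoulli-polys
#' @export
k4 <- function(x) {
  h <- x - 0.5
  h2 <- h * h
  (h2 * h2 - h2 / 2 + 7 / 240) / 24
}

#' Study-day time domain
#'
#' Holds the observed study window; all spline computations run on time
#' rescaled affinely to \eqn{[0,1]} over this window.
#'
#' @param day_min,day_max integer study days, \code{day_min < day_max}.
#' @return an object of class \code{"time_domain"}.
#' @export
#' @examples
#' dom <- time_domain(0, 160)
#' scale_time(80, dom)
time_domain <- function(day_min, day_max) {
  stopifnot(is.numeric(day_min), is.numeric(day_max), length(day_min) == 1L,
            length(day_max) == 1L, is.finite(day_min), is.finite(day_max))
  if (day_min >= day_max)
    stop("time_domain: day_min must be strictly less than day_max")
  structure(list(day_min = day_min, day_max = day_max), class = "time_domain")
}

#' Map study days to scaled time in [0,1]
#'
#' Affine, order-preserving map \eqn{(d - d_{\min})/(d_{\max} - d_{\min})}.
#' Days outside the domain are an error: the spline is not extrapolated.
#'
#' @param day numeric vector of study days.
#' @param domain a \code{\link{time_domain}}.
#' @return numeric vector in \eqn{[0,1]}.
#' @export
scale_time <- function(day, domain) {
  stopifnot(inherits(domain, "time_domain"))
  if (any(!is.finite(day)))
    stop("scale_time: non-finite day")
  if (any(day < domain$day_min | day > domain$day_max))
    stop(sprintf("scale_time: day outside domain [%s, %s]",
                 domain$day_min, domain$day_max))
  (day - domain$day_min) / (domain$day_max - domain$day_min)
}

#' Cubic-spline reproducing kernel on the unit interval
#'
#' \eqn{K(s,t) = k_2(s)k_2(t) - k_4(|s-t|)}.  Symmetric, and every Gram
#' matrix built from it is positive semidefinite.  Vectorised over
#' \code{s} and \code{t} elementwise (recycled).
#'
#' @param s,t scaled times in \eqn{[0,1]}.
#' @return kernel values.
#' @export
#' @examples
#' cubic_kernel(0, 0)      # 1/120
#' cubic_kernel(0.5, 0.5)  # 1/320
cubic_kernel <- function(s, t) {
  if (any(s < 0 | s > 1) || any(t < 0 | t > 1))
    stop("cubic_kernel: arguments must lie in [0, 1]")
  k2(s) * k2(t) - k4(abs(s - t))
}

# n1 x n2 kernel Gram block, vectorised
cubic_kernel_matrix <- function(s, t) {
  outer(k2(s), k2(t)) - k4(abs(outer(s, t, "-")))
}

#' Zero-mean group contrast
#'
#' Codes the two-level group factor as +1/2 (treatment, PEER) and -1/2
#' (control), so that group main effect and interaction average to zero over
#' the two levels -- the ANOVA identifiability side condition.
#'
#' @param g character vector of group labels.
#' @param treat the label coded +1/2.
#' @param ctrl the label coded -1/2.
#' @return numeric vector of +-1/2.
#' @export
group_contrast <- function(g, treat = "PEER", ctrl = "control") {
  g <- as.character(g)
  out <- rep(NA_real_, length(g))
  out[g == treat] <- 0.5
  out[g == ctrl] <- -0.5
  if (any(is.na(out)))
    stop(sprintf("group_contrast: unknown group level(s): %s",
                 paste(unique(g[is.na(out)]), collapse = ", ")))
  out
}

#' Penalized-term kernel for the time x group decomposition
#'
#' Evaluates the reproducing kernel of one penalized SSANOVA term between two
#' design points: \code{"time_main"} is the cubic kernel in scaled time;
#' \code{"interaction"} multiplies it by the product of the group contrasts.
#' Each is scaled by the nonnegative term multiplier \code{theta}.
#'
#' @param t1,t2 scaled times in \eqn{[0,1]}.
#' @param gc1,gc2 group contrast values (\eqn{\pm 1/2}).
#' @param term \code{"time_main"} or \code{"interaction"}.
#' @param theta nonnegative term-scale multiplier.
#' @return kernel values.
#' @export
term_kernel <- function(t1, gc1, t2, gc2,
                        term = c("time_main", "interaction"), theta = 1) {
  term <- match.arg(term)
  if (theta < 0) stop("term_kernel: theta must be nonnegative")
  base <- cubic_kernel(t1, t2)
  if (term == "interaction") base <- base * gc1 * gc2
  theta * base
}

# Combined-penalty Gram block between (t1, gc1) rows and (t2, gc2) columns:
#   theta[1] * K(t,t') + theta[2] * K(t,t') * c(g) c(g')
term_gram <- function(t1, gc1, t2, gc2, theta = c(1, 1)) {
  Kt <- cubic_kernel_matrix(t1, t2)
  theta[1] * Kt + theta[2] * Kt * outer(gc1, gc2)
}

#' Unpenalized (null-space) basis
#'
#' The functions carrying no roughness penalty: the constant, the linear time
#' trend \eqn{k_1(t)}, the parametric group contrast, and their product (the
#' linear part of the interaction).  Returns an \eqn{n \times 4} matrix.
#'
#' @param t scaled times.
#' @param gc group contrast values.
#' @return matrix with columns \code{const}, \code{time}, \code{group},
#'   \code{time:group}.
#' @export
null_basis <- function(t, gc) {
  cbind(const = rep(1, length(t)), time = k1(t), group = gc,
        `time:group` = k1(t) * gc)
}
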
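#' Principal hyperfine tensor of a doxyl spin label
#'
#' Literature single-crystal values for doxyl stearate probes,
#' Axx = Ayy = 6.1 G, Azz = 32.9 G. With these constants the
#' polarity-corrected order-parameter formula reproduces published
#' 5-doxyl-stearic-acid tables to within +-0.005; [calibrate_tensor()] can
#' refine them against reference S values when exactness matters.
#'
#' @param axx,ayy,azz principal hyperfine values (G), Azz > Axx, Ayy > 0.
#' @return `mp_tensor` list with axx, ayy, azz.
#' @export
tensor_constants <- function(axx = 6.1, ayy = 6.1, azz = 32.9) {
  if (any(c(axx, ayy, azz) <= 0) || azz <= max(axx, ayy))
    stop("need Azz > Axx, Ayy > 0")
  structure(list(axx = axx, ayy = ayy, azz = azz), class = "mp_tensor")
}

#' Spin-label order parameter from hyperfine extrema
#'
#' Polarity-corrected order parameter of a nitroxide spin probe,
#' \deqn{S = \frac{A_\parallel - A_\perp}{A_{zz} - (A_{xx}+A_{yy})/2}
#'   \cdot \frac{a_0}{a'},\quad
#'   a' = \frac{A_\parallel + 2A_\perp}{3},\quad
#'   a_0 = \frac{A_{xx}+A_{yy}+A_{zz}}{3},}
#' from the outer (2A_par) and inner (2A_perp) hyperfine splittings of the
#' spectrum. S near 1 marks a rigid environment, lower values a fluid one;
#' values outside [0, 1] are flagged as unphysical.
#'
#' @param two_A_par outer splitting 2A_par (G), one value or a vector.
#' @param two_A_perp inner splitting 2A_perp (G); requires
#'   `two_A_par > two_A_perp > 0`.
#' @param tensor a [tensor_constants()].
#' @return data.frame with S, a0, a_prime (G) and `physical` flag.
#' @export
order_parameter <- function(two_A_par, two_A_perp,
                            tensor = tensor_constants()) {
  if (any(!(two_A_par > two_A_perp & two_A_perp > 0)))
    stop("need 2A_par > 2A_perp > 0")
  A_par <- two_A_par / 2; A_perp <- two_A_perp / 2
  a0 <- (tensor$axx + tensor$ayy + tensor$azz) / 3
  a_prime <- (A_par + 2 * A_perp) / 3
  S <- (A_par - A_perp) / (tensor$azz - (tensor$axx + tensor$ayy) / 2) *
    (a0 / a_prime)
  data.frame(S = S, a0 = a0, a_prime = a_prime,
             physical = S >= 0 & S <= 1)
}

#' Rotational correlation time from a rotational diffusion tensor
#'
#' \deqn{\tau_c = \frac{1}{6\,(D_x D_y D_z)^{1/3}},} the geometrically
#' averaged correlation time of anisotropic rotational diffusion. Invariant
#' under permutation of the tensor elements; scaling D by c scales tau_c by
#' 1/c.
#'
#' @param D_x,D_y,D_z rotational diffusion rates (s^-1, > 0).
#' @return tau_c in ns.
#' @export
rotational_correlation_time <- function(D_x, D_y, D_z) {
  if (any(c(D_x, D_y, D_z) <= 0)) stop("diffusion rates must be > 0")
  1 / (6 * (D_x * D_y * D_z)^(1 / 3)) * 1e9
}

#' Calibrate hyperfine tensor constants against reference S values
#'
#' Only the ratio \eqn{c = a_0 / [A_{zz} - (A_{xx}+A_{yy})/2]} enters the
#' order-parameter formula, so the tensor is identifiable from S records up
#' to that ratio: this routine least-squares fits c over all records
#' (\eqn{S_i = c\,(A_{\parallel,i}-A_{\perp,i})/a'_i}), holds Axx = Ayy at
#' the literature value and solves Azz from the fitted ratio.
#'
#' @param records data.frame with columns `two_A_par_G`, `two_A_perp_G` and
#'   reference `S_ref`; at least two distinct records.
#' @param axx fixed Axx = Ayy value (G).
#' @return list with `tensor` ([tensor_constants()]), `ratio` (fitted c),
#'   `residuals` (fitted minus reference S per record).
#' @export
calibrate_tensor <- function(records, axx = 6.1) {
  need <- c("two_A_par_G", "two_A_perp_G", "S_ref")
  if (!all(need %in% names(records)))
    stop("records must have columns ", paste(need, collapse = ", "))
  if (nrow(records) < 2) stop("need at least 2 records")
  A_par <- records$two_A_par_G / 2
  A_perp <- records$two_A_perp_G / 2
  x <- (A_par - A_perp) / ((A_par + 2 * A_perp) / 3)
  if (max(x) - min(x) < 1e-12) stop("degenerate records: identical splittings")
  ratio <- sum(x * records$S_ref) / sum(x^2)
  if (3 * ratio <= 1) stop("fitted ratio incompatible with a physical tensor")
  azz <- (3 * axx * ratio + 2 * axx) / (3 * ratio - 1)
  tensor <- tensor_constants(axx, axx, azz)
  fitted <- order_parameter(records$two_A_par_G, records$two_A_perp_G, tensor)$S
  list(tensor = tensor, ratio = ratio, residuals = fitted - records$S_ref)
}

#' Write / read a hyperfine-extrema table
#'
#' CSV with header `sample, two_A_par_G, two_A_perp_G` (extra columns such
#' as `S_ref` are preserved). The writer validates that every row satisfies
#' 2A_par > 2A_perp > 0; round trip through the reader is lossless.
#'
#' @param records data.frame with at least sample, two_A_par_G, two_A_perp_G.
#' @param path CSV path.
#' @return `path` (write) / the table (read).
#' @export
write_epr_table <- function(records, path) {
  need <- c("sample", "two_A_par_G", "two_A_perp_G")
  if (!all(need %in% names(records)))
    stop("records must have columns ", paste(need, collapse = ", "))
  if (nrow(records)) {
    if (!is.numeric(records$two_A_par_G) || !is.numeric(records$two_A_perp_G) ||
        any(!is.finite(records$two_A_par_G)) || any(!is.finite(records$two_A_perp_G)))
      stop("splittings must be finite numbers")
    if (any(!(records$two_A_par_G > records$two_A_perp_G &
              records$two_A_perp_G > 0)))
      stop("every row needs 2A_par > 2A_perp > 0")
  }
  utils::write.csv(records, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname write_epr_table
#' @export
read_epr_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample", "two_A_par_G", "two_A_perp_G")
  if (!all(need %in% names(tab)))
    stop("EPR table must have columns ", paste(need, collapse = ", "))
  tab
}

#' Order parameters for a whole hyperfine table
#'
#' Applies [order_parameter()] to every row; appends tau_c when diffusion
#' tensor columns (`D_x`, `D_y`, `D_z`, s^-1) are present.
#'
#' @param records table as from [read_epr_table()].
#' @param tensor a [tensor_constants()].
#' @return records with S, a0, a_prime (and tau_c_ns when derivable) added.
#' @export
epr_analysis <- function(records, tensor = tensor_constants()) {
  if (!nrow(records)) return(records)
  op <- order_parameter(records$two_A_par_G, records$two_A_perp_G, tensor)
  out <- cbind(records, op)
  if (all(c("D_x", "D_y", "D_z") %in% names(records)))
    out$tau_c_ns <- rotational_correlation_time(records$D_x, records$D_y,
                                                records$D_z)
  out
}
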
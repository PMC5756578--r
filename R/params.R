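#' Model parameters for the linked-particle system
#'
#' Bundles the physical parameters shared by the particle simulator, the
#' macroscopic aggregation-diffusion solvers and the stability analysis.
#' The spatial domain is the periodic box `[-L, L]` in each of `dim`
#' dimensions.  Particles (or density) diffuse with noise intensity `D` and
#' attract/repel each other through elastic links: a link between particles at
#' distance `r` stores energy `(kappa/2) * (r - ell)^2`, and links can only
#' form between particles closer than the detection radius `R`.
#'
#' In the fast linking/unlinking regime the link network equilibrates
#' instantaneously and the net pairwise interaction is described by the
#' compactly supported potential [spring_potential()]; its Fourier modes on
#' the box drive the linear stability of the uniform state.
#'
#' @param D Noise intensity (scaled units), `D >= 0`.
#' @param ell Equilibrium spring length, `0 <= ell < R`.
#' @param R Detection radius for link formation, `0 < R <= L`.
#' @param L Domain half-size; the domain is `[-L, L]` per dimension.
#' @param kappa Spring constant (the scaled model fixes `kappa = 2`).
#' @param nu_f Linking frequency, `> 0`.
#' @param nu_d Unlinking frequency, `> 0`.
#' @param mu Mobility (fixed to 1 in the scaled model).
#' @param dim Spatial dimension, 1 or 2.
#'
#' @return An object of class `"net_params"`: a list with the above fields
#'   plus the derived ratio `alpha = ell / R`.
#' @examples
#' p <- net_params(D = 0.003, ell = 0.4725)
#' p$alpha
#' @export
net_params <- function(D = 0.003, ell = 0.3, R = 0.75, L = 3,
                       kappa = 2, nu_f = 1, nu_d = 1, mu = 1, dim = 1L) {
  stopifnot(is.numeric(D), length(D) == 1L, is.finite(D),
            is.numeric(ell), length(ell) == 1L, is.finite(ell),
            is.numeric(R), length(R) == 1L, is.numeric(L), length(L) == 1L)
  if (D < 0) stop("noise intensity 'D' must be >= 0")
  if (R <= 0 || R > L) stop("detection radius must satisfy 0 < R <= L")
  if (dim == 1L && R >= L) stop("the 1D analysis requires R < L")
  if (ell < 0 || ell >= R) stop("spring length must satisfy 0 <= ell < R")
  if (kappa <= 0) stop("'kappa' must be > 0")
  if (nu_f <= 0 || nu_d <= 0) stop("linking/unlinking frequencies must be > 0")
  if (!dim %in% c(1L, 2L)) stop("'dim' must be 1 or 2")
  structure(
    list(D = D, ell = ell, R = R, L = L, kappa = kappa,
         nu_f = nu_f, nu_d = nu_d, mu = mu, dim = as.integer(dim),
         alpha = ell / R),
    class = "net_params")
}

#' @export
print.net_params <- function(x, ...) {
  cat(sprintf("<net_params> %dD periodic box [-%g, %g]\n", x$dim, x$L, x$L))
  cat(sprintf("  D = %g, ell = %g, R = %g (alpha = %.4f)\n",
              x$D, x$ell, x$R, x$alpha))
  cat(sprintf("  kappa = %g, nu_f = %g, nu_d = %g, mu = %g\n",
              x$kappa, x$nu_f, x$nu_d, x$mu))
  invisible(x)
}

#' Serialize parameters to a flat key-value config file
#'
#' Writes one `key = value` pair per line.  Extra named values (solver
#' settings such as `n_cells`, `delta`, `tol`, `seed`) may be appended via
#' `...`; [read_config()] restores everything as a named list with
#' `params` rebuilt through [net_params()].
#'
#' @param params A [net_params()] object.
#' @param path File to write.
#' @param ... Additional scalar settings to record.
#' @return `path`, invisibly.
#' @export
write_config <- function(params, path, ...) {
  extra <- list(...)
  vals <- c(params[c("D", "ell", "R", "L", "kappa", "nu_f", "nu_d",
                     "mu", "dim")], extra)
  lines <- sprintf("%s = %s", names(vals),
                   vapply(vals, function(v) format(v, digits = 17), ""))
  writeLines(lines, path)
  invisible(path)
}

#' Read a flat key-value config file
#'
#' @param path File written by [write_config()] (or hand-edited in the same
#'   `key = value` format).
#' @return A named list with element `params` (a [net_params()] object) and
#'   any extra settings found in the file.
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^\\s*#", lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  keys <- vapply(kv, function(x) trimws(x[[1L]]), "")
  vals <- lapply(kv, function(x) {
    v <- trimws(paste(x[-1L], collapse = "="))
    num <- suppressWarnings(as.numeric(v))
    if (is.na(num)) v else num
  })
  names(vals) <- keys
  pnames <- c("D", "ell", "R", "L", "kappa", "nu_f", "nu_d", "mu", "dim")
  have <- intersect(pnames, keys)
  params <- do.call(net_params, vals[have])
  c(list(params = params), vals[setdiff(keys, pnames)])
}
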
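#' The eight constrained model variants
#'
#' Each variant of the simple DDM either shares a parameter across the
#' cued and miscued conditions or lets it differ in the direction of a
#' positive cueing effect: non-decision time shorter when cued
#' (t0c <= t0m), starting point shifted toward the cued side
#' (zc >= 0.5 with zm = 1 - zc), drift higher when cued (vc >= vm).
#' Boundary separation `a` is shared in every variant; when the starting
#' point does not vary it is fixed at 0.5.
#'
#' The directional constraints are enforced by construction through the
#' free-parameter vector: nonnegative gaps `delta_t0` (t0m = t0 + delta_t0,
#' with t0 the cued value) and `delta_v` (vc = v + delta_v, with v the
#' miscued value), and a cued starting point `z_c` in `[0.5, 1)`.
#'
#' @return `model_catalogue()`: a named list of the 8 `ddm_model_spec`
#'   objects, in order simple, t0, z, v, z-v, t0-v, t0-z, complex.
#' @examples
#' names(model_catalogue())
#' free_parameter_count(model_catalogue()$complex)
#' @export
model_catalogue <- function() {
  mk <- function(name, t0_varies, z_varies, v_varies) {
    free <- c("v", "a", "t0",
              if (t0_varies) "delta_t0",
              if (z_varies) "z_c",
              if (v_varies) "delta_v")
    structure(list(name = name, t0_varies = t0_varies, z_varies = z_varies,
                   v_varies = v_varies, free_params = free,
                   constraint_map = list(
                     t0 = if (t0_varies) "t0c<t0m" else "t0c=t0m",
                     z  = if (z_varies) "zc>0.5,zm=1-zc" else "z=0.5",
                     v  = if (v_varies) "vc>vm" else "vc=vm",
                     a  = "ac=am")),
              class = "ddm_model_spec")
  }
  specs <- list(
    simple  = mk("simple",  FALSE, FALSE, FALSE),
    t0      = mk("t0",      TRUE,  FALSE, FALSE),
    z       = mk("z",       FALSE, TRUE,  FALSE),
    v       = mk("v",       FALSE, FALSE, TRUE),
    `z-v`   = mk("z-v",     FALSE, TRUE,  TRUE),
    `t0-v`  = mk("t0-v",    TRUE,  FALSE, TRUE),
    `t0-z`  = mk("t0-z",    TRUE,  TRUE,  FALSE),
    complex = mk("complex", TRUE,  TRUE,  TRUE))
  specs
}

#' @export
print.ddm_model_spec <- function(x, ...) {
  cat(sprintf("<ddm_model_spec> %s: free = {%s}; %s\n", x$name,
              paste(x$free_params, collapse = ", "),
              paste(unlist(x$constraint_map), collapse = "; ")))
  invisible(x)
}

#' @rdname model_catalogue
#' @param spec a `ddm_model_spec`.
#' @export
free_parameter_count <- function(spec) {
  stopifnot(inherits(spec, "ddm_model_spec"))
  length(spec$free_params)
}

#' Expand a free-parameter vector to condition-specific DDM parameters
#'
#' Maps a model variant's free parameters to the (cued, miscued) pair of
#' [ddm_params()] under the variant's constraints. Shared parameters are
#' bit-identical across conditions.
#'
#' @param spec a `ddm_model_spec` from [model_catalogue()].
#' @param fv named numeric vector supplying exactly `spec$free_params`.
#' @param s diffusion coefficient.
#' @return `list(cued = , miscued = )` of [ddm_params()].
#' @examples
#' expand_parameters(model_catalogue()$t0,
#'                   c(v = 2, a = 1.5, t0 = 0.28, delta_t0 = 0.04))
#' @export
expand_parameters <- function(spec, fv, s = 1) {
  stopifnot(inherits(spec, "ddm_model_spec"))
  fv <- unlist(fv)
  if (!setequal(names(fv), spec$free_params) ||
      length(fv) != length(spec$free_params))
    stop("free vector must supply exactly {",
         paste(spec$free_params, collapse = ", "), "} for model '",
         spec$name, "'", call. = FALSE)
  fv <- fv[spec$free_params]
  d_t0 <- if (spec$t0_varies) fv[["delta_t0"]] else 0
  d_v  <- if (spec$v_varies) fv[["delta_v"]] else 0
  z_c  <- if (spec$z_varies) fv[["z_c"]] else 0.5
  if (d_t0 < 0 || d_v < 0)
    stop("gap parameters must be nonnegative", call. = FALSE)
  if (z_c < 0.5 || z_c >= 1)
    stop("`z_c` must lie in [0.5, 1)", call. = FALSE)
  list(
    cued    = ddm_params(v = fv[["v"]] + d_v, a = fv[["a"]], z = z_c,
                         t0 = fv[["t0"]], s = s),
    miscued = ddm_params(v = fv[["v"]], a = fv[["a"]], z = 1 - z_c,
                         t0 = fv[["t0"]] + d_t0, s = s))
}

# free-vector matrix (rows = proposals, cols = spec$free_params) to the
# 7-column parameter matrix ddm_loglik_cpp expects:
# v_c, v_m, a, z_c, z_m, t0_c, t0_m
expand_matrix <- function(theta, spec) {
  cn <- spec$free_params
  v <- theta[, match("v", cn)]
  a <- theta[, match("a", cn)]
  t0 <- theta[, match("t0", cn)]
  d_t0 <- if (spec$t0_varies) theta[, match("delta_t0", cn)] else 0
  z_c <- if (spec$z_varies) theta[, match("z_c", cn)] else 0.5
  d_v <- if (spec$v_varies) theta[, match("delta_v", cn)] else 0
  cbind(v + d_v, v, a, z_c + numeric(nrow(theta)), 1 - z_c, t0, t0 + d_t0)
}

#' Serialise the model catalogue
#'
#' Writes the catalogue (names, free parameters, constraint map) as JSON
#' so fitted runs record the exact constraint set used.
#'
#' @param path output file; if `NULL`, the JSON string is returned.
#' @export
write_model_catalogue <- function(path = NULL) {
  cat_ <- lapply(model_catalogue(), function(sp)
    list(name = sp$name, free_params = sp$free_params,
         constraints = sp$constraint_map))
  js <- jsonlite::toJSON(cat_, auto_unbox = TRUE, pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(path)
}
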
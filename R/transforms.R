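#' Resistance-surface parameterizations
#'
#' A `resistance_spec` describes how one landscape layer becomes a resistance
#' surface. Categorical layers assign one value per class with one reference
#' class held fixed at 1 and the remaining free values searched in
#' `[0.01, 3500]`. Continuous layers are first rescaled to `[0, 10]` and then
#' passed through a Monomolecular (saturating) or Ricker (hump-shaped)
#' transformation with positive `shape` and `maximum` parameters. A
#' `composite_spec` is an ordered list of component specs combined by
#' cellwise sum.
#'
#' @param name surface name.
#' @param values named numeric vector of per-class resistance values; classes
#'   are the names. Exactly the class in `fixed` must have value 1.
#' @param fixed class label held at resistance 1 (default the first name).
#' @return a `resistance_spec`.
#' @export
categorical_spec <- function(name, values, fixed = names(values)[1]) {
  if (is.null(names(values)) || anyDuplicated(names(values)))
    stop("values must be uniquely named by class")
  if (!fixed %in% names(values)) stop("fixed class not among classes")
  if (abs(values[[fixed]] - 1) > 1e-12)
    stop("the fixed class must have resistance exactly 1")
  free <- values[setdiff(names(values), fixed)]
  clamped <- free < 0.01
  if (any(clamped)) {
    warning("free class values below 0.01 clamped to 0.01: ",
            paste(names(free)[clamped], collapse = ", "))
    values[names(free)[clamped]] <- 0.01
  }
  if (any(values > 3500))
    stop("class resistance values must be <= 3500")
  structure(list(name = name, kind = "categorical",
                 values = values, fixed = fixed),
            class = "resistance_spec")
}

#' @rdname categorical_spec
#' @param transformation `"monomolecular"` or `"ricker"`.
#' @param shape,maximum positive transformation parameters (shape on the
#'   `[0, 10]` rescaled layer domain; maximum in resistance units).
#' @export
continuous_spec <- function(name, transformation = c("monomolecular", "ricker"),
                            shape, maximum) {
  transformation <- match.arg(transformation)
  if (!is.numeric(shape) || shape <= 0 || !is.numeric(maximum) || maximum <= 0)
    stop("shape and maximum must be positive")
  structure(list(name = name, kind = "continuous",
                 transformation = transformation,
                 shape = as.numeric(shape), maximum = as.numeric(maximum)),
            class = "resistance_spec")
}

#' @rdname categorical_spec
#' @param components list of `resistance_spec` (length >= 2).
#' @export
composite_spec <- function(components, name = "composite") {
  if (length(components) < 2L) stop("a composite needs >= 2 components")
  for (s in components)
    if (!inherits(s, "resistance_spec")) stop("components must be resistance_spec")
  structure(list(name = name, kind = "composite", components = components),
            class = c("composite_spec", "resistance_spec"))
}

#' @export
print.resistance_spec <- function(x, ...) {
  if (x$kind == "categorical")
    cat(sprintf("<resistance_spec> %s (categorical): %s [%s fixed at 1]\n",
                x$name,
                paste(sprintf("%s=%g", names(x$values), x$values), collapse = ", "),
                x$fixed))
  else if (x$kind == "continuous")
    cat(sprintf("<resistance_spec> %s (%s): shape=%g, maximum=%g\n",
                x$name, x$transformation, x$shape, x$maximum))
  else {
    cat(sprintf("<composite_spec> %s, %d components:\n", x$name,
                length(x$components)))
    for (s in x$components) print(s)
  }
  invisible(x)
}

#' Serialize / deserialize a resistance spec as YAML
#' @param spec a `resistance_spec` or `composite_spec`.
#' @param path file path.
#' @return `path` (write) or the spec (read).
#' @export
write_spec_yaml <- function(spec, path) {
  to_list <- function(s) {
    if (s$kind == "composite")
      list(name = s$name, kind = "composite",
           components = lapply(s$components, to_list))
    else if (s$kind == "categorical")
      list(name = s$name, kind = "categorical", fixed = s$fixed,
           values = as.list(s$values))
    else
      list(name = s$name, kind = "continuous",
           transformation = s$transformation,
           shape = s$shape, maximum = s$maximum)
  }
  yaml::write_yaml(to_list(spec), path)
  invisible(path)
}

#' @rdname write_spec_yaml
#' @export
read_spec_yaml <- function(path) {
  from_list <- function(l) {
    if (l$kind == "composite")
      composite_spec(lapply(l$components, from_list), name = l$name)
    else if (l$kind == "categorical")
      categorical_spec(l$name, unlist(l$values), fixed = l$fixed)
    else
      continuous_spec(l$name, l$transformation, l$shape, l$maximum)
  }
  from_list(yaml::read_yaml(path))
}

#' Rescale a continuous layer onto a fixed range
#'
#' Affine map of the non-nodata values onto `[lower, upper]` (default
#' `[0, 10]`, the domain on which the transformation shape parameter is
#' defined), so shape and maximum are comparable across layers with
#' different native units.
#'
#' @param grid a `land_grid` with at least two distinct values.
#' @param lower,upper target range.
#' @return rescaled `land_grid`.
#' @export
rescale_layer <- function(grid, lower = 0, upper = 10) {
  v <- grid$values
  rng <- range(v, na.rm = TRUE)
  if (!is.finite(rng[1]) || rng[1] == rng[2])
    stop("constant grid cannot be rescaled")
  out <- lower + (v - rng[1]) / (rng[2] - rng[1]) * (upper - lower)
  land_grid(out, grid$cell_size, grid$origin, grid$nodata)
}

#' Continuous resistance transformations
#'
#' Monomolecular: `f(x) = maximum * (1 - exp(-x / shape))`, saturating and
#' strictly increasing. Ricker: `f(x) = maximum * x * exp(-x / shape)`,
#' hump-shaped with its mode at `x = shape`. The output is re-anchored so the
#' easiest cell has resistance exactly 1:
#' `R(x) = f(x) - min(f) + 1`.
#'
#' @param grid `land_grid` rescaled to `[0, 10]` (see [rescale_layer()]).
#' @param transformation `"monomolecular"` or `"ricker"`.
#' @param shape,maximum positive parameters.
#' @return resistance `land_grid` with minimum exactly 1.
#' @export
apply_continuous <- function(grid, transformation = c("monomolecular", "ricker"),
                             shape, maximum) {
  transformation <- match.arg(transformation)
  if (shape <= 0 || maximum <= 0) stop("shape and maximum must be positive")
  x <- grid$values
  f <- switch(transformation,
              monomolecular = maximum * (1 - exp(-x / shape)),
              ricker = maximum * x * exp(-x / shape))
  f <- f - min(f, na.rm = TRUE) + 1
  land_grid(f, grid$cell_size, grid$origin, grid$nodata)
}

#' Categorical resistance assignment
#'
#' Pure lookup of per-class resistance values from a [categorical_spec()];
#' the fixed reference class maps to 1.
#'
#' @param grid `land_grid` of class codes.
#' @param spec a categorical `resistance_spec` covering every class present.
#' @return resistance `land_grid`.
#' @export
apply_categorical <- function(grid, spec) {
  stopifnot(inherits(spec, "resistance_spec"), spec$kind == "categorical")
  v <- grid$values
  present <- as.character(unique(v[!is.na(v)]))
  miss <- setdiff(present, names(spec$values))
  if (length(miss))
    stop("classes present in grid but not in spec: ", paste(miss, collapse = ", "))
  out <- v
  ok <- !is.na(v)
  out[ok] <- unname(spec$values[as.character(v[ok])])
  land_grid(out, grid$cell_size, grid$origin, grid$nodata)
}

#' Combine component resistance surfaces into a composite
#'
#' Cellwise sum of component resistances, re-anchored so the minimum cell is
#' exactly 1 (the MLPE slope absorbs overall scale, so the anchor fixes an
#' identifiability gauge, not the fit).
#'
#' @param components list of resistance `land_grid`s on one georeference.
#' @return composite resistance `land_grid`.
#' @export
combine_composite <- function(components) {
  if (length(components) < 2L) stop("need >= 2 component surfaces")
  .check_georef(components)
  s <- components[[1]]$values
  for (g in components[-1]) s <- s + g$values
  s <- s - min(s, na.rm = TRUE) + 1
  land_grid(s, components[[1]]$cell_size, components[[1]]$origin,
            components[[1]]$nodata)
}

#' Build a resistance surface from a spec and its layer
#'
#' Dispatch helper used throughout the pipeline: categorical specs look up
#' class values, continuous specs rescale the layer to `[0, 10]` and apply
#' the transformation, composite specs build each component and combine.
#'
#' @param spec a `resistance_spec` or `composite_spec`.
#' @param layers for a single spec, one `land_grid`; for a composite, a named
#'   list of `land_grid`s keyed by component surface name.
#' @return resistance `land_grid`.
#' @export
build_resistance <- function(spec, layers) {
  if (spec$kind == "composite") {
    comps <- lapply(spec$components, function(s) {
      lay <- layers[[s$name]]
      if (is.null(lay)) stop("no layer supplied for component ", s$name)
      build_resistance(s, lay)
    })
    return(combine_composite(comps))
  }
  grid <- if (inherits(layers, "land_grid")) layers else layers[[spec$name]]
  if (spec$kind == "categorical") apply_categorical(grid, spec)
  else apply_continuous(rescale_layer(grid), spec$transformation,
                        spec$shape, spec$maximum)
}
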
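## Bimodal phantom generator: a geometric foreground on a flat
## background, Gaussian intensity noise, then impulse (salt/pepper)
## contamination placed uniformly over the canvas. Gives every other
## module a ground-truthed test image without external data.

#' Construct a PhantomSpec
#'
#' Defaults describe a lesion-like disk covering roughly a fifth of a
#' 100 x 100 canvas, dark background (60) and bright foreground (190)
#' separated by well over the Gaussian noise scale (sigma 10), with no
#' impulse noise unless requested.
#'
#' @param height,width canvas size in pixels.
#' @param geometry foreground shape: \code{"disk"}, \code{"ellipse"} or
#'   \code{"rectangle"}.
#' @param center foreground center \code{c(row, col)}; defaults to the
#'   canvas center.
#' @param radii half-extents \code{c(row, col)} for ellipse/rectangle; a
#'   disk uses the first entry. Defaults to a quarter of the smaller
#'   canvas side.
#' @param muBg,muFg mean gray values of background and foreground (must
#'   differ).
#' @param sigma Gaussian noise standard deviation in gray levels.
#' @param saltDensity,pepperDensity fractions of pixels forced to
#'   255 / 0; must sum below 1.
#' @param seed RNG seed; generation is bit-reproducible given the spec.
#' @return a [PhantomSpec-class].
#' @examples
#' phantomSpec(saltDensity = 0.05, pepperDensity = 0.05, seed = 7)
#' @export
phantomSpec <- function(height = 100L, width = 100L, geometry = "disk",
                        center = c((height + 1) / 2, (width + 1) / 2),
                        radii = rep(min(height, width) / 4, 2L),
                        muBg = 60, muFg = 190, sigma = 10,
                        saltDensity = 0, pepperDensity = 0, seed = 1L) {
    if (length(radii) == 1L) radii <- rep(radii, 2L)
    new("PhantomSpec", height = as.integer(height),
        width = as.integer(width), geometry = geometry,
        center = as.numeric(center), radii = as.numeric(radii),
        muBg = muBg, muFg = muFg, sigma = sigma,
        saltDensity = saltDensity, pepperDensity = pepperDensity,
        seed = as.integer(seed))
}

.phantomMask <- function(spec) {
    r <- matrix(seq_len(spec@height), spec@height, spec@width)
    c_ <- matrix(seq_len(spec@width), spec@height, spec@width, byrow = TRUE)
    dr <- r - spec@center[1L]
    dc <- c_ - spec@center[2L]
    inside <- switch(spec@geometry,
        disk = dr^2 + dc^2 <= spec@radii[1L]^2,
        ellipse = (dr / spec@radii[1L])^2 + (dc / spec@radii[2L])^2 <= 1,
        rectangle = abs(dr) <= spec@radii[1L] & abs(dc) <= spec@radii[2L])
    if (!any(inside))
        stop("degenerate phantom: foreground geometry does not intersect the canvas")
    matrix(as.integer(inside), spec@height, spec@width)
}

## run expr under the spec's seed without disturbing the caller's RNG
.withSeed <- function(seed, expr) {
    has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
        if (has) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(),
                        inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
    expr
}

#' Generate a bimodal phantom image with its ground truth
#'
#' Pixels are drawn as \code{clip(round(N(mu_region, sigma)), 0, 255)};
#' afterwards \code{round(saltDensity * N)} pixels chosen uniformly are
#' forced to 255 and \code{round(pepperDensity * N)} further pixels to 0
#' (Gaussian first, impulses overwrite, so the histogram tail masses are
#' exact). The same seed always yields a bit-identical image.
#'
#' @param spec a [PhantomSpec-class].
#' @return list with elements \code{image} ([GrayImage-class]) and
#'   \code{mask} (the generating ground-truth [BinaryMask-class]).
#' @export
generatePhantom <- function(spec) {
    stopifnot(is(spec, "PhantomSpec"))
    mask <- .phantomMask(spec)
    n <- spec@height * spec@width
    .withSeed(spec@seed, {
        mu <- ifelse(mask == 1L, spec@muFg, spec@muBg)
        p <- round(mu + stats::rnorm(n, 0, spec@sigma))
        p <- pmin(pmax(p, 0), 255)
        nSalt <- round(spec@saltDensity * n)
        nPepper <- round(spec@pepperDensity * n)
        if (nSalt + nPepper > 0) {
            idx <- sample.int(n, nSalt + nPepper)
            if (nSalt > 0) p[idx[seq_len(nSalt)]] <- 255
            if (nPepper > 0) p[idx[nSalt + seq_len(nPepper)]] <- 0
        }
        list(image = grayImage(matrix(as.integer(p), spec@height,
                                      spec@width)),
             mask = binaryMask(mask))
    })
}

#' Reference decision boundary of a phantom
#'
#' The equal-variance two-Gaussian Bayes boundary up to the class-prior
#' term: the midpoint of the two region means. Used as the recovery
#' target when checking that threshold estimates land near the generating
#' optimum.
#'
#' @param spec a [PhantomSpec-class].
#' @return \code{(muBg + muFg) / 2}. With \code{sigma = 0} any threshold
#'   strictly between the two levels is optimal; the midpoint is returned.
#' @export
bayesThreshold <- function(spec) {
    stopifnot(is(spec, "PhantomSpec"))
    (spec@muBg + spec@muFg) / 2
}

#' Serialize / deserialize a PhantomSpec as JSON
#'
#' @param spec a [PhantomSpec-class].
#' @param path file path.
#' @return \code{writePhantomSpec} returns the path invisibly;
#'   \code{readPhantomSpec} returns a [PhantomSpec-class].
#' @export
writePhantomSpec <- function(spec, path) {
    stopifnot(is(spec, "PhantomSpec"))
    x <- list(height = spec@height, width = spec@width,
              geometry = spec@geometry, center = spec@center,
              radii = spec@radii, muBg = spec@muBg, muFg = spec@muFg,
              sigma = spec@sigma, saltDensity = spec@saltDensity,
              pepperDensity = spec@pepperDensity, seed = spec@seed)
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
    invisible(path)
}

#' @rdname writePhantomSpec
#' @export
readPhantomSpec <- function(path) {
    x <- jsonlite::read_json(path, simplifyVector = TRUE)
    phantomSpec(height = x$height, width = x$width, geometry = x$geometry,
                center = x$center, radii = x$radii, muBg = x$muBg,
                muFg = x$muFg, sigma = x$sigma,
                saltDensity = x$saltDensity,
                pepperDensity = x$pepperDensity, seed = x$seed)
}
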
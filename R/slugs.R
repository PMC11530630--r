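# Slug sets: piecewise-constant mixture profiles along a channel.
#
# A slug is a contiguous interval of a channel occupied by one homogeneous
# mixture. A slug set stores the interface positions as fractions of channel
# length (0 = node_a end, 1 = node_b end) together with one concentration row
# per slug, so plug-flow advection is a pure rescaling of positions and the
# intervals always partition [0, 1] exactly.

.pos_tol <- 1e-12
.merge_tol <- 1e-12

#' Construct a slug set
#'
#' @param bounds ascending numeric vector of interface positions; must start
#'   at 0 and end at 1.
#' @param conc concentration matrix with one row per slug (i.e.
#'   `length(bounds) - 1` rows) and one named column per species, in mol/m^3.
#'   A named vector is accepted for a single slug.
#' @return an object of class `mf_slugs`.
#' @export
slug_set <- function(bounds, conc) {
  if (is.null(dim(conc))) {
    conc <- matrix(conc, nrow = 1, dimnames = list(NULL, names(conc)))
  }
  bounds <- as.numeric(bounds)
  if (length(bounds) != nrow(conc) + 1L) {
    stop("need one concentration row per slug interval")
  }
  if (abs(bounds[1]) > .pos_tol || abs(bounds[length(bounds)] - 1) > .pos_tol ||
      any(diff(bounds) <= 0)) {
    stop("bounds must increase strictly from 0 to 1")
  }
  bounds[1] <- 0; bounds[length(bounds)] <- 1
  structure(list(b = bounds, C = conc), class = "mf_slugs")
}

#' @rdname slug_set
#' @param conc named concentration vector for a channel filled with a single
#'   uniform mixture.
#' @export
uniform_slug_set <- function(conc) {
  slug_set(c(0, 1), matrix(conc, nrow = 1, dimnames = list(NULL, names(conc))))
}

#' @export
print.mf_slugs <- function(x, ...) {
  cat("<mf_slugs>", nrow(x$C), "slug(s)\n")
  df <- data.frame(start = x$b[-length(x$b)], end = x$b[-1])
  print(cbind(df, as.data.frame(x$C)))
  invisible(x)
}

# Reverse the coordinate (p -> 1 - p); used to run all transport code in the
# flow direction regardless of the channel's stored orientation.
flip_slugs <- function(s) {
  k <- length(s$b)
  structure(list(b = rev(1 - s$b),
                 C = s$C[rev(seq_len(nrow(s$C))), , drop = FALSE]),
            class = "mf_slugs")
}

# Volume-weighted mean concentration of the whole slug set (one value per
# species).
slug_mean_conc <- function(s) {
  w <- diff(s$b)
  colSums(s$C * w)
}

# Total amount per species in a compartment of total volume V holding this
# profile.
slug_moles <- function(s, volume) slug_mean_conc(s) * volume

# Merge adjacent slugs whose concentrations agree within a relative
# tolerance per species; bounds slug counts over long runs. An optional
# second matrix (the mirrored tank profile) is merged jointly: two cells
# merge only if both profiles agree there.
merge_slug_set <- function(s, tol = .merge_tol, partner = NULL) {
  k <- nrow(s$C)
  if (k < 2) return(if (is.null(partner)) s else list(x = s, y = partner))
  test <- s$C
  if (!is.null(partner)) test <- cbind(test, partner$C)
  d <- abs(test[-1, , drop = FALSE] - test[-k, , drop = FALSE])
  m <- pmax(abs(test[-1, , drop = FALSE]), abs(test[-k, , drop = FALSE]))
  same <- rowSums(d > tol * m) == 0
  if (!any(same)) return(if (is.null(partner)) s else list(x = s, y = partner))
  grp <- cumsum(c(TRUE, !same))
  keep <- c(TRUE, !same, TRUE)
  nb <- s$b[keep]
  w <- diff(s$b)
  wg <- as.numeric(rowsum(w, grp))
  collapse <- function(C) {
    M <- rowsum(C * w, grp) / wg
    colnames(M) <- colnames(C)
    M
  }
  x <- structure(list(b = nb, C = collapse(s$C)), class = "mf_slugs")
  if (is.null(partner)) return(x)
  y <- structure(list(b = nb, C = collapse(partner$C)), class = "mf_slugs")
  list(x = x, y = y)
}

#' Advect a slug set by plug flow
#'
#' Translates every slug interface downstream by the fraction
#' `shift = |Q| dt / V` of the channel length, attributes the volume leaving
#' the channel slug by slug to the downstream node, and fills the inlet with
#' a new slug carrying the current node-outflow mixture. Species amount is
#' conserved exactly: what enters plus what was stored equals what is stored
#' plus what left. Positions are in flow coordinates (0 = inlet, 1 = outlet);
#' callers flip the set first for channels with negative flow.
#'
#' @param slugs an `mf_slugs` object oriented with the flow.
#' @param shift fraction of the channel length advected, in `[0, 1]`.
#' @param inlet_mix named concentration vector entering at the inlet.
#' @param merge_tol relative tolerance below which adjacent slugs are merged.
#' @return list with the updated `slugs` and `outflow`, a list of
#'   `(conc, volume_fraction)` records in the order the material left.
#' @export
propagate_slugs <- function(slugs, shift, inlet_mix, merge_tol = .merge_tol) {
  if (shift < 0 || shift > 1 + .pos_tol) stop("shift must lie in [0, 1]")
  shift <- min(shift, 1)
  b <- slugs$b; C <- slugs$C
  k <- nrow(C)
  if (shift <= .pos_tol) return(list(slugs = slugs, outflow = list()))
  cut <- 1 - shift
  ex <- pmax(0, b[-1] - pmax(b[-(k + 1)], cut))
  out_idx <- rev(which(ex > .pos_tol))       # nearest the outlet leaves first
  outflow <- lapply(out_idx, function(i) {
    list(conc = C[i, ], volume_fraction = ex[i])
  })
  if (shift >= 1 - .pos_tol) {
    new <- uniform_slug_set(inlet_mix)
  } else {
    kept <- which(b[-(k + 1)] < cut - .pos_tol)   # cells overlapping [0, cut)
    inner <- b[b > .pos_tol & b < cut - .pos_tol]
    nb <- c(0, shift, inner + shift, 1)
    nC <- rbind(inlet_mix, C[kept, , drop = FALSE])
    colnames(nC) <- colnames(C)
    new <- structure(list(b = nb, C = nC), class = "mf_slugs")
  }
  list(slugs = merge_slug_set(new, merge_tol), outflow = outflow)
}

#' Mirror-and-recycle rotation of a tank profile
#'
#' The tank attached to a membrane has no advective flow of its own, but its
#' contents are kept mirrored against the channel slugs: when the channel
#' advances by a fraction `shift`, the tank profile is rotated by the same
#' fraction, and the material that would exit at the downstream end re-enters
#' at the upstream front in order. No tank material is created or destroyed.
#'
#' @param tank_slugs `mf_slugs` profile of the tank, in the attached
#'   channel's flow coordinates.
#' @param shift rotation fraction in `[0, 1)`.
#' @return the rotated `mf_slugs` profile.
#' @export
mirror_and_recycle <- function(tank_slugs, shift) {
  shift <- shift %% 1
  if (shift <= .pos_tol || shift >= 1 - .pos_tol) return(tank_slugs)
  if (nrow(tank_slugs$C) == 1) return(tank_slugs)   # uniform: rotation is id
  b <- tank_slugs$b; C <- tank_slugs$C
  k <- nrow(C)
  a <- b[-(k + 1)] + shift
  e <- b[-1] + shift
  starts <- numeric(0); ends <- numeric(0); rows <- integer(0)
  for (i in seq_len(k)) {
    if (e[i] <= 1 + .pos_tol) {
      starts <- c(starts, a[i]); ends <- c(ends, min(e[i], 1)); rows <- c(rows, i)
    } else if (a[i] >= 1 - .pos_tol) {
      starts <- c(starts, a[i] - 1); ends <- c(ends, e[i] - 1); rows <- c(rows, i)
    } else {
      starts <- c(starts, a[i], 0); ends <- c(ends, 1, e[i] - 1)
      rows <- c(rows, i, i)
    }
  }
  o <- order(starts)
  starts <- starts[o]; ends <- ends[o]; rows <- rows[o]
  nb <- c(starts, 1)
  nb[1] <- 0; nb[length(nb)] <- 1
  structure(list(b = nb, C = C[rows, , drop = FALSE]), class = "mf_slugs")
}

#' Impose a common partition on two slug sets
#'
#' Splits both profiles at the union of their interface positions so that
#' they share identical bounds cell by cell (the alignment the membrane
#' exchange step requires). Splitting never changes either profile's content.
#'
#' @param x,y `mf_slugs` objects over the same channel.
#' @return list of the two re-partitioned `mf_slugs` objects `x` and `y`.
#' @export
align_slug_sets <- function(x, y) {
  nb <- sort(c(x$b, y$b))
  nb <- nb[c(TRUE, diff(nb) > .pos_tol)]
  nb[1] <- 0; nb[length(nb)] <- 1
  mid <- (nb[-1] + nb[-length(nb)]) / 2
  pick <- function(s) {
    idx <- findInterval(mid, s$b, rightmost.closed = TRUE)
    idx <- pmin(pmax(idx, 1L), nrow(s$C))
    structure(list(b = nb, C = s$C[idx, , drop = FALSE]), class = "mf_slugs")
  }
  list(x = pick(x), y = pick(y))
}
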
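#' Electrode montage
#'
#' A montage is an ordered set of scalp electrode labels from the extended
#' international 10-10 system together with their idealized positions on a
#' unit sphere (head radius normalized to 1, vertex at `Cz = (0, 0, 1)`,
#' `x` toward the right ear, `y` toward the nasion). Positions are used only
#' for spatial mixing of simulated sources and for topographic neighbor
#' queries; no anatomical forward model is implied.
#'
#' @param channel_names Character vector of unique 10-10 labels. Must include
#'   at least `C3`, `Cz` and `C4`.
#' @param positions Numeric matrix, one row per channel, columns `x`, `y`,
#'   `z`; every row must have unit norm (within `1e-9`). If omitted, the
#'   positions are derived from the labels by [electrode_position()].
#' @return An object of class `montage`: a list with `channel_names` and the
#'   `positions` matrix (rownames = labels).
#' @examples
#' m <- montage(c("C3", "Cz", "C4"))
#' m$positions
#' @export
montage <- function(channel_names, positions = NULL) {
  channel_names <- as.character(channel_names)
  assert_that(anyDuplicated(channel_names) == 0, "montage channel names must be unique")
  assert_that(all(c("C3", "Cz", "C4") %in% channel_names),
              "montage must contain at least C3, Cz and C4")
  if (is.null(positions)) {
    positions <- t(vapply(channel_names, electrode_position, numeric(3)))
  }
  positions <- as.matrix(positions)
  assert_that(nrow(positions) == length(channel_names) && ncol(positions) == 3,
              "positions must be an n x 3 matrix matching channel_names")
  r <- sqrt(rowSums(positions^2))
  assert_that(all(abs(r - 1) < 1e-9), "electrode positions must lie on the unit sphere")
  dimnames(positions) <- list(channel_names, c("x", "y", "z"))
  structure(list(channel_names = channel_names, positions = positions),
            class = "montage")
}

#' @export
print.montage <- function(x, ...) {
  cat("<montage> ", length(x$channel_names), " channels: ",
      paste(utils::head(x$channel_names, 8), collapse = ", "),
      if (length(x$channel_names) > 8) ", ..." else "", "\n", sep = "")
  invisible(x)
}

# Row letters -> fractional anterior coordinate of the idealized 10-10 grid.
.row_ap <- c(Fp = 0.8, AF = 0.6, F = 0.4, FC = 0.2, C = 0, CP = -0.2,
             P = -0.4, PO = -0.6, O = -0.8, I = -1.0)
# Prefixes that alias into another row at the 10% lateral ring.
.row_alias <- c(T = "C", FT = "FC", TP = "CP")

#' Idealized unit-sphere position of a 10-10 electrode label
#'
#' Maps a label to a point on the unit sphere by the azimuthal-equidistant
#' convention: the row letter fixes the anterior-posterior coordinate, the
#' digit the lateral one (odd = left), and the polar angle from the vertex
#' grows linearly with radial fraction (10% of the nasion-inion arc = 18
#' degrees), so `C3`/`C4` sit 36 degrees from `Cz` and `T7`/`T8` 72 degrees.
#'
#' @param label A 10-10 label such as `"C3"`, `"FCz"`, `"TP8"`.
#' @return Numeric length-3 vector `(x, y, z)`.
#' @export
electrode_position <- function(label) {
  m <- regmatches(label, regexec("^([A-Za-z]+?)(z|[0-9]+)$", label))[[1]]
  assert_that(length(m) == 3, paste0("cannot parse electrode label '", label, "'"))
  row <- m[2]
  if (row %in% names(.row_alias)) row <- .row_alias[[row]]
  assert_that(row %in% names(.row_ap), paste0("unknown 10-10 row in label '", label, "'"))
  a <- .row_ap[[row]]
  if (m[3] == "z") {
    l <- 0
  } else {
    d <- as.integer(m[3])
    l <- 0.2 * ceiling(d / 2) * if (d %% 2 == 1) -1 else 1
  }
  rho <- sqrt(a^2 + l^2)
  theta <- rho * pi / 2  # 18 degrees per 0.2 of radial fraction
  if (rho < 1e-12) return(c(0, 0, 1))
  c(sin(theta) * l / rho, sin(theta) * a / rho, cos(theta))
}

#' Built-in montages
#'
#' Reduced and full idealized 10-10 layouts. `"standard19"` is the classic
#' 10-20 set and the package default (desk-scale simulations); `"standard32"`
#' adds the intermediate FC/CP and AF/PO rows; `"standard64"` is the full
#' 10-10 grid plus `Iz`, `TP9`, `TP10`.
#'
#' @param layout One of `"standard19"`, `"standard32"`, `"standard64"`.
#' @return A [montage()].
#' @export
standard_montage <- function(layout = c("standard19", "standard32", "standard64")) {
  layout <- match.arg(layout)
  ch <- switch(layout,
    standard19 = c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8", "T7", "C3",
                   "Cz", "C4", "T8", "P7", "P3", "Pz", "P4", "P8", "O1", "O2"),
    standard32 = c("Fp1", "Fpz", "Fp2", "F7", "F3", "Fz", "F4", "F8",
                   "FC5", "FC1", "FC2", "FC6", "T7", "C3", "Cz", "C4", "T8",
                   "CP5", "CP1", "CP2", "CP6", "P7", "P3", "Pz", "P4", "P8",
                   "PO3", "POz", "PO4", "O1", "Oz", "O2"),
    standard64 = c("Fp1", "Fpz", "Fp2",
                   "AF7", "AF3", "AFz", "AF4", "AF8",
                   "F7", "F5", "F3", "F1", "Fz", "F2", "F4", "F6", "F8",
                   "FT7", "FC5", "FC3", "FC1", "FCz", "FC2", "FC4", "FC6", "FT8",
                   "T7", "C5", "C3", "C1", "Cz", "C2", "C4", "C6", "T8",
                   "TP9", "TP7", "CP5", "CP3", "CP1", "CPz", "CP2", "CP4",
                   "CP6", "TP8", "TP10",
                   "P7", "P5", "P3", "P1", "Pz", "P2", "P4", "P6", "P8",
                   "PO7", "PO3", "POz", "PO4", "PO8",
                   "O1", "Oz", "O2", "Iz"))
  montage(ch)
}

# Great-circle distance (radians) between every channel and a reference point.
great_circle_dist <- function(positions, ref) {
  d <- positions %*% ref
  acos(pmin(1, pmax(-1, as.numeric(d))))
}
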
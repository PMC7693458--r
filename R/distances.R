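# Among-individual colour distances, computed within each floral patch.

#' Angular distance between two hues
#'
#' Shortest arc between two angles on the circle, in degrees within
#' `[0, 180]`. In the hexagon model the angular distance between two loci is
#' the difference in colour hue, while the Euclidean distance is a proxy for
#' chromatic contrast.
#'
#' @param theta_a,theta_b Hue angles in degrees (vectorised). `NA` inputs
#'   (undefined hues) propagate to `NA`.
#' @return Degrees in `[0, 180]`.
#' @examples
#' angular_distance(350, 10)  # 20
#' @export
angular_distance <- function(theta_a, theta_b) {
  d <- abs(theta_a - theta_b) %% 360
  pmin(d, 360 - d)
}

#' Pairwise among-individual colour distances within each patch
#'
#' For each floral patch, computes the Euclidean (hexagon units) and angular
#' (degrees) distance between the colour loci of every unordered pair of
#' plants: `n(n-1)/2` records per patch. Plants missing any patch are
#' dropped with a warning (the distance design must be complete); pairs
#' involving an undefined hue get `NA` angular distance and are counted in
#' the `"angular_excluded"` attribute.
#'
#' @param tbl A [patch_colors()] table.
#' @return Data frame with columns `patch`, `structure`, `position`,
#'   `plant_a`, `plant_b`, `euclidean`, `angular`.
#' @export
pairwise_distances <- function(tbl) {
  stopifnot(is.data.frame(tbl))
  counts <- table(tbl$plant_id)
  complete <- names(counts)[counts == length(.PATCHES)]
  ok <- complete[vapply(complete, function(p)
    setequal(tbl$patch[tbl$plant_id == p], .PATCHES), logical(1))]
  dropped <- setdiff(unique(tbl$plant_id), ok)
  if (length(dropped))
    warning(sprintf("dropping %d plant(s) with incomplete patch sets: %s",
                    length(dropped), paste(utils::head(dropped, 5), collapse = ", ")))
  if (length(ok) < 2L) stop("need at least 2 complete plants for pairwise distances")
  plants <- sort(ok)
  pairs <- utils::combn(plants, 2L)
  excluded <- 0L
  res <- lapply(.PATCHES, function(pt) {
    sub <- tbl[tbl$patch == pt & tbl$plant_id %in% plants, ]
    sub <- sub[match(plants, sub$plant_id), ]
    ia <- match(pairs[1L, ], plants)
    ib <- match(pairs[2L, ], plants)
    eu <- sqrt((sub$x[ia] - sub$x[ib])^2 + (sub$y[ia] - sub$y[ib])^2)
    an <- angular_distance(sub$hue_deg[ia], sub$hue_deg[ib])
    excluded <<- excluded + sum(is.na(an))
    data.frame(patch = pt, structure = .patch_structure(pt),
               position = .patch_position(pt),
               plant_a = pairs[1L, ], plant_b = pairs[2L, ],
               euclidean = eu, angular = an, row.names = NULL)
  })
  out <- do.call(rbind, res)
  attr(out, "angular_excluded") <- excluded
  out
}
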
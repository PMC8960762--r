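#' Landmark set for one ear specimen
#'
#' Bundles the named 3D points and ordered landmark rings digitised from a CT
#' scan of one middle ear. Coordinates are in millimetres. Named points are
#' the umbo (apex of the tympanic membrane), the columella tip, the
#' extrastapedius tip and base, and the centre of the columella footplate.
#' Rings are ordered circuits of at least three points outlining the tympanic
#' rim, footplate rim, round-window rim and cochlear-aqueduct rim.
#'
#' @param specimen_id character scalar identifying the specimen.
#' @param species character scalar, species name.
#' @param points named list of numeric length-3 vectors (mm).
#' @param rings named list of numeric matrices with 3 columns (mm), each with
#'   at least 3 rows, rows in circuit order.
#' @return An object of class `"ear_landmarks"`.
#' @export
landmark_set <- function(specimen_id, species, points = list(),
                         rings = list()) {
  stopifnot(is.character(specimen_id), length(specimen_id) == 1L,
            is.character(species), length(species) == 1L)
  points <- lapply(points, function(p) {
    p <- as.numeric(p)
    if (length(p) != 3L || !all(is.finite(p)))
      stop("each landmark point must be a finite 3D coordinate", call. = FALSE)
    p
  })
  rings <- lapply(rings, function(r) {
    r <- as.matrix(r)
    storage.mode(r) <- "double"
    if (ncol(r) != 3L)
      stop("rings must be matrices with 3 columns (x, y, z)", call. = FALSE)
    if (nrow(r) < 3L)
      stop("rings must contain at least 3 points", call. = FALSE)
    if (!all(is.finite(r)))
      stop("ring coordinates must all be finite", call. = FALSE)
    dimnames(r) <- NULL
    r
  })
  structure(list(specimen_id = specimen_id, species = species,
                 points = points, rings = rings),
            class = "ear_landmarks")
}

#' @export
print.ear_landmarks <- function(x, ...) {
  cat("Ear landmark set: specimen", x$specimen_id,
      sprintf("(%s)\n", x$species))
  cat("  points:", paste(names(x$points), collapse = ", "), "\n")
  rn <- vapply(x$rings, nrow, integer(1))
  cat("  rings: ",
      paste(sprintf("%s [%d]", names(x$rings), rn), collapse = ", "), "\n")
  invisible(x)
}

.as_ring <- function(ring) {
  r <- as.matrix(ring)
  storage.mode(r) <- "double"
  if (ncol(r) != 3L) stop("ring must have 3 columns", call. = FALSE)
  if (nrow(r) < 3L)
    stop("degenerate ring: fewer than 3 points", call. = FALSE)
  if (!all(is.finite(r))) stop("ring has non-finite coordinates", call. = FALSE)
  r
}

#' Total-least-squares base plane of a landmark ring
#'
#' Fits the plane minimising the sum of squared orthogonal distances to the
#' ring points (via singular value decomposition of the centred coordinates).
#' The plane origin is the ring centroid; the normal is the singular vector of
#' the smallest singular value. The returned object also carries an
#' orthonormal in-plane basis used for 2D projection.
#'
#' @param ring numeric matrix, one 3D point (mm) per row, at least 3 rows.
#' @return Object of class `"ear_plane"`: list with `origin` (centroid),
#'   `normal` (unit vector), `basis` (3 x 2 in-plane basis) and `rms_residual`.
#' @export
fit_base_plane <- function(ring) {
  r <- .as_ring(ring)
  ctr <- colMeans(r)
  x <- sweep(r, 2L, ctr)
  sv <- svd(x)
  # collinear (or coincident) points: no unique plane
  if (sv$d[2L] <= max(sv$d[1L], 1) * 1e-10)
    stop("degenerate ring: points are collinear", call. = FALSE)
  normal <- sv$v[, 3L]
  normal <- normal / sqrt(sum(normal^2))
  structure(list(origin = ctr, normal = normal, basis = sv$v[, 1:2],
                 rms_residual = sqrt(mean((x %*% normal)^2))),
            class = "ear_plane")
}

# project 3D points onto a plane's 2D in-plane coordinates
.project2d <- function(pts, plane) {
  pts <- rbind(pts)
  dimnames(pts) <- NULL
  sweep(pts, 2L, plane$origin) %*% plane$basis
}

# signed distance(s) from points to plane along the normal
.plane_dist <- function(pts, plane) {
  pts <- rbind(pts)
  dimnames(pts) <- NULL
  drop(sweep(pts, 2L, plane$origin) %*% plane$normal)
}

# TRUE when any two non-adjacent edges of a closed 2D polygon cross
.polygon_self_intersects <- function(xy) {
  n <- nrow(xy)
  a <- xy
  b <- xy[c(2:n, 1L), , drop = FALSE]
  idx <- which(outer(seq_len(n), seq_len(n),
                     function(i, j) j > i + 1L & !(i == 1L & j == n)),
               arr.ind = TRUE)
  if (nrow(idx) == 0L) return(FALSE)
  i <- idx[, 1L]; j <- idx[, 2L]
  p <- a[i, , drop = FALSE]; p2 <- b[i, , drop = FALSE]
  q <- a[j, , drop = FALSE]; q2 <- b[j, , drop = FALSE]
  cross2 <- function(u, v) u[, 1L] * v[, 2L] - u[, 2L] * v[, 1L]
  d1 <- cross2(p2 - p, q - p)
  d2 <- cross2(p2 - p, q2 - p)
  d3 <- cross2(q2 - q, p - q)
  d4 <- cross2(q2 - q, p2 - q)
  any(d1 * d2 < 0 & d3 * d4 < 0)
}

#' Area enclosed by a landmark ring
#'
#' Projects the ring onto its own total-least-squares base plane and applies
#' the shoelace formula to the projected polygon. The result is invariant to
#' rigid motion of the ring and always non-negative.
#'
#' @param ring numeric matrix of ordered 3D points (mm).
#' @param ring_name optional name used in error messages.
#' @return Area in mm^2.
#' @export
ring_area <- function(ring, ring_name = "ring") {
  r <- .as_ring(ring)
  pl <- fit_base_plane(r)
  xy <- .project2d(r, pl)
  if (.polygon_self_intersects(xy))
    stop(sprintf("projected polygon of '%s' is self-intersecting", ring_name),
         call. = FALSE)
  n <- nrow(xy)
  j <- c(2:n, 1L)
  abs(sum(xy[, 1L] * xy[j, 2L] - xy[j, 1L] * xy[, 2L])) / 2
}

#' Umbo height above the tympanic rim plane
#'
#' Unsigned orthogonal distance from the umbo to the base plane of the
#' tympanic rim; quantifies conical protrusion of the eardrum.
#'
#' @param tympanic_rim ring matrix (mm).
#' @param umbo numeric length-3 point (mm).
#' @return Height in mm.
#' @export
umbo_height <- function(tympanic_rim, umbo) {
  pl <- fit_base_plane(tympanic_rim)
  abs(.plane_dist(umbo, pl))
}

#' Mean tympanic membrane angle
#'
#' For each rim point, the angle between the segment running from that point
#' to the umbo and the rim's base plane; the trait is the mean over rim
#' points, in degrees. A flat membrane gives 0; a right cone with apex height
#' equal to rim radius gives 45.
#'
#' @inheritParams umbo_height
#' @return Angle in degrees, in \[0, 90\].
#' @export
membrane_angle <- function(tympanic_rim, umbo) {
  r <- .as_ring(tympanic_rim)
  pl <- fit_base_plane(r)
  v <- sweep(-r, 2L, as.numeric(umbo), FUN = "+")  # rim point -> umbo vectors
  len <- sqrt(rowSums(v^2))
  if (any(len < 1e-12))
    stop("umbo coincides with a rim point", call. = FALSE)
  s <- pmin(1, abs(v %*% pl$normal) / len)
  mean(asin(s)) * 180 / pi
}

#' Columella offset from the eardrum centre
#'
#' In-plane distance between the projection of the columella tip onto the
#' tympanic-rim base plane and the projected rim centroid. A centrally placed
#' columella gives 0; larger values indicate a stronger second-order lever.
#'
#' @param tympanic_rim ring matrix (mm).
#' @param columella_tip numeric length-3 point (mm).
#' @return Offset in mm.
#' @export
columella_offset <- function(tympanic_rim, columella_tip) {
  pl <- fit_base_plane(tympanic_rim)
  xy <- .project2d(columella_tip, pl)      # centroid projects to (0, 0)
  sqrt(sum(xy^2))
}

#' Lever arms of the tympanic membrane
#'
#' The fulcrum is taken as the rim point nearest the in-plane projection of
#' the columella tip. `l1` is the in-plane distance from the fulcrum to the
#' projected umbo (extracolumella tip); `l2` from the fulcrum to the projected
#' columella tip. Their ratio `l1/l2` is the second-order lever gain and tends
#' to 1 as the columella offset vanishes.
#'
#' @param tympanic_rim ring matrix (mm).
#' @param columella_tip,umbo numeric length-3 points (mm).
#' @return Named list with `l1`, `l2` (mm) and `ratio`.
#' @export
lever_arms <- function(tympanic_rim, columella_tip, umbo) {
  r <- .as_ring(tympanic_rim)
  pl <- fit_base_plane(r)
  rim2 <- .project2d(r, pl)
  tip2 <- drop(.project2d(columella_tip, pl))
  umb2 <- drop(.project2d(umbo, pl))
  d <- sqrt(rowSums(sweep(rim2, 2L, tip2)^2))
  f <- rim2[which.min(d), ]
  l2 <- sqrt(sum((f - tip2)^2))
  if (l2 < 1e-12)
    stop("columella tip projects onto the fulcrum (l2 = 0)", call. = FALSE)
  l1 <- sqrt(sum((f - umb2)^2))
  list(l1 = l1, l2 = l2, ratio = l1 / l2)
}

#' Euclidean distance between two landmarks
#'
#' @param p,q numeric length-3 points (mm).
#' @return Distance in mm.
#' @export
segment_length <- function(p, q) {
  p <- as.numeric(p); q <- as.numeric(q)
  stopifnot(length(p) == 3L, length(q) == 3L,
            all(is.finite(p)), all(is.finite(q)))
  sqrt(sum((p - q)^2))
}

.required_points <- c("umbo", "columella_tip", "extrastapedius_tip",
                      "columella_footplate_center", "extrastapedius_base")
.required_rings <- c("tympanic_rim", "footplate_rim", "round_window_rim",
                     "cochlear_aqueduct_rim")

#' Measure all continuous ear traits of one specimen
#'
#' Computes the continuous middle-ear measures from a landmark set: the four
#' aperture areas (tympanic membrane, columella footplate, round window,
#' cochlear aqueduct), the tympanic-membrane-to-footplate area ratio, umbo
#' height, mean membrane angle, columella offset, the two lever arms and
#' their ratio, extrastapedius length, and columella length.
#'
#' @param lm an [landmark_set()] object with all required points and rings.
#' @return One-row data frame with `species`, the measure columns and
#'   `n_specimens = 1`.
#' @export
measure_specimen <- function(lm) {
  stopifnot(inherits(lm, "ear_landmarks"))
  mp <- setdiff(.required_points, names(lm$points))
  if (length(mp))
    stop("missing landmark point(s): ", paste(mp, collapse = ", "),
         call. = FALSE)
  mr <- setdiff(.required_rings, names(lm$rings))
  if (length(mr))
    stop("missing landmark ring(s): ", paste(mr, collapse = ", "),
         call. = FALSE)
  p <- lm$points; rg <- lm$rings
  tm_area <- ring_area(rg$tympanic_rim, "tympanic_rim")
  fp_area <- ring_area(rg$footplate_rim, "footplate_rim")
  lev <- lever_arms(rg$tympanic_rim, p$columella_tip, p$umbo)
  data.frame(
    species = lm$species,
    tympanic_membrane_area = tm_area,
    footplate_area = fp_area,
    area_ratio = tm_area / fp_area,
    round_window_area = ring_area(rg$round_window_rim, "round_window_rim"),
    cochlear_aqueduct_area = ring_area(rg$cochlear_aqueduct_rim,
                                       "cochlear_aqueduct_rim"),
    umbo_height = umbo_height(rg$tympanic_rim, p$umbo),
    tympanic_membrane_angle = membrane_angle(rg$tympanic_rim, p$umbo),
    columella_offset = columella_offset(rg$tympanic_rim, p$columella_tip),
    lever_arm_l1 = lev$l1,
    lever_arm_l2 = lev$l2,
    lever_ratio = lev$ratio,
    extrastapedius_length = segment_length(p$extrastapedius_base,
                                           p$extrastapedius_tip),
    columella_length = segment_length(p$columella_tip,
                                      p$columella_footplate_center),
    n_specimens = 1L,
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Aggregate specimen records to a species mean
#'
#' Arithmetic mean per measure over specimens of one species; the two ratio
#' fields are recomputed from the averaged components so that the record's
#' internal consistency (area_ratio = TM area / footplate area, lever_ratio =
#' l1/l2) is preserved.
#'
#' @param records data frame of [measure_specimen()] rows, all one species.
#' @return One-row data frame with `n_specimens` set to the number of rows.
#' @export
species_mean <- function(records) {
  stopifnot(is.data.frame(records))
  if (nrow(records) == 0L) stop("no records to average", call. = FALSE)
  sp <- unique(records$species)
  if (length(sp) != 1L)
    stop("records mix species: ", paste(sp, collapse = ", "), call. = FALSE)
  out <- records[1L, , drop = FALSE]
  for (m in .ear_measures) out[[m]] <- mean(records[[m]])
  out$area_ratio <- out$tympanic_membrane_area / out$footplate_area
  out$lever_ratio <- out$lever_arm_l1 / out$lever_arm_l2
  out$n_specimens <- nrow(records)
  rownames(out) <- NULL
  out
}

#' Build a species trait table from specimen landmark sets
#'
#' Measures every specimen and averages within species.
#'
#' @param landmark_sets list of [landmark_set()] objects.
#' @return Data frame, one row per species, ordered by species name.
#' @export
measure_all <- function(landmark_sets) {
  recs <- do.call(rbind, lapply(landmark_sets, measure_specimen))
  out <- do.call(rbind, lapply(split(recs, recs$species), species_mean))
  out <- out[order(out$species), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read a fiducial landmark CSV (Slicer markups dialect)
#'
#' Parses a per-specimen fiducial file: comment header lines begin with `#`
#' (the last of which may declare `# columns = ...`), data rows hold at least
#' `label`, `x`, `y`, `z`. Ring membership is encoded in the label as
#' `ringname-<k>` with `<k>` giving circuit order; any label without such a
#' numeric suffix is a named point.
#'
#' @param path file path.
#' @param specimen_id,species identifiers; default to the file base name.
#' @return An [landmark_set()] object.
#' @export
read_fcsv <- function(path, specimen_id = NULL, species = NULL) {
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^#", lines, value = TRUE)
  body <- lines[!grepl("^#", lines) & nzchar(lines)]
  cols <- NULL
  cdecl <- grep("columns *=", hdr, value = TRUE)
  if (length(cdecl)) {
    cols <- strsplit(sub(".*columns *= *", "", cdecl[length(cdecl)]),
                     ",")[[1]]
    cols <- trimws(cols)
  }
  df <- read.csv(text = paste(body, collapse = "\n"),
                 header = is.null(cols), stringsAsFactors = FALSE)
  if (!is.null(cols)) {
    if (ncol(df) != length(cols))
      stop("fiducial file column declaration does not match data",
           call. = FALSE)
    names(df) <- cols
  }
  need <- c("label", "x", "y", "z")
  if (!all(need %in% names(df)))
    stop("fiducial file must provide columns label, x, y, z", call. = FALSE)
  if (is.null(specimen_id))
    specimen_id <- sub("\\.f?csv$", "", basename(path))
  if (is.null(species)) species <- specimen_id
  is_ring <- grepl("-[0-9]+$", df$label)
  pts <- list()
  for (i in which(!is_ring))
    pts[[df$label[i]]] <- c(df$x[i], df$y[i], df$z[i])
  rings <- list()
  if (any(is_ring)) {
    rname <- sub("-[0-9]+$", "", df$label[is_ring])
    rord <- as.integer(sub("^.*-", "", df$label[is_ring]))
    for (nm in unique(rname)) {
      sel <- which(is_ring)[rname == nm]
      sel <- sel[order(rord[rname == nm])]
      rings[[nm]] <- as.matrix(df[sel, c("x", "y", "z")])
    }
  }
  landmark_set(specimen_id, species, pts, rings)
}

#' Write a landmark set as a fiducial CSV
#'
#' Inverse of [read_fcsv()]; round-trips points and ring order.
#'
#' @param lm an [landmark_set()] object.
#' @param path output file path.
#' @export
write_fcsv <- function(lm, path) {
  stopifnot(inherits(lm, "ear_landmarks"))
  rows <- list()
  for (nm in names(lm$points)) {
    p <- lm$points[[nm]]
    rows[[length(rows) + 1L]] <- data.frame(label = nm, x = p[1], y = p[2],
                                            z = p[3])
  }
  for (nm in names(lm$rings)) {
    r <- lm$rings[[nm]]
    rows[[length(rows) + 1L]] <- data.frame(
      label = sprintf("%s-%d", nm, seq_len(nrow(r))),
      x = r[, 1], y = r[, 2], z = r[, 3])
  }
  df <- do.call(rbind, rows)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# Markups fiducial file (earmorph dialect)",
               "# columns = label,x,y,z"), con)
  write.table(df, con, sep = ",", row.names = FALSE, col.names = FALSE,
              quote = FALSE)
}
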
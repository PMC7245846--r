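#' Specification of a synthetic thorax phantom
#'
#' Describes one synthetic mouse-thorax micro-CT acquisition: stack
#' geometry, disease model and severity, and the in-plane pose (rotation
#' and translation) that emulates variation in animal positioning in the
#' scanner. All geometry is defined in fractions of the stack size, so
#' scaled-down phantoms (e.g. 256 or 128 voxels per edge) are
#' proportionally identical to the default 512-slice, 512x512 geometry.
#'
#' @param n_slices number of axial slices (default 512, minimum 16).
#' @param slice_shape length-2 integer, rows x cols per slice.
#' @param voxel_size_mm isotropic voxel edge in mm.
#' @param disease one of `"control"`, `"fibrosis"`, `"emphysema"`,
#'   `"lps"`.
#' @param severity disease severity in `[0, 1]`; 0 is indistinguishable
#'   from control at the voxel level.
#' @param rotation_deg in-plane rotation of the animal; `NULL` (default)
#'   samples U(-10, 10). Must lie in (-45, 45).
#' @param shift_px in-plane translation (row, col) in voxels; `NULL`
#'   samples U(-15, 15) per axis, scaled with the slice size so that
#'   small phantoms keep the same relative positioning tolerance.
#' @param rng_seed integer seed; the phantom is fully deterministic given
#'   the spec.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(n_slices = 512L, slice_shape = c(512L, 512L),
                         voxel_size_mm = 0.04,
                         disease = c("control", "fibrosis", "emphysema", "lps"),
                         severity = 0, rotation_deg = NULL, shift_px = NULL,
                         rng_seed = 1L) {
  disease <- match.arg(disease)
  if (n_slices < 16L) stop("n_slices must be >= 16")
  if (length(slice_shape) != 2L || any(slice_shape < 16L))
    stop("slice_shape must be two values >= 16")
  if (severity < 0 || severity > 1) stop("severity must be in [0, 1]")
  if (!is.null(rotation_deg) && abs(rotation_deg) >= 45)
    stop("rotation must be within (-45, 45) degrees")
  structure(list(n_slices = as.integer(n_slices),
                 slice_shape = as.integer(slice_shape),
                 voxel_size_mm = voxel_size_mm, disease = disease,
                 severity = severity, rotation_deg = rotation_deg,
                 shift_px = shift_px, rng_seed = as.integer(rng_seed)),
            class = "phantom_spec")
}

# Anatomical layout of the phantom, in fractions of slice extent (rows,
# cols) and stack depth (z). Intensity means/SDs sit inside the raw-value
# ranges that aerated parenchyma (~1000-1500) and dense/fibrotic tissue
# (~2000-2500) occupy on the target scanner; bone sits above both, air
# and airway lumen below.
phantom_geometry <- function() {
  list(
    body    = list(row = 0.50, col = 0.50, a = 0.42, b = 0.42,
                   z = c(0.05, 0.95)),
    lung_z  = c(0.25, 0.75),
    lungs   = list(
      right = list(row = 0.50, col = 0.30, a = 0.238, b = 0.190),
      left  = list(row = 0.50, col = 0.70, a = 0.214, b = 0.167)),
    drift   = 0.02,
    sternum = list(row = 0.30, col = 0.50, r = 0.024),
    spine   = list(row = 0.70, col = 0.50, r = 0.035),
    trachea = list(row = 0.46, col = 0.50, r = 0.012, z = c(0.10, 0.25)),
    bronchi = list(r = 0.010, z = c(0.25, 0.40), end_col_off = 0.16,
                   end_row = 0.50),
    mu = c(air = 300, parenchyma = 1250, airway = 350, soft = 2250,
           bone = 3200, fibrotic = 2250),
    sd = c(air = 50, parenchyma = 120, airway = 50, soft = 120,
           bone = 150, fibrotic = 120)
  )
}

#' The five lung-part slice classes
#' @export
slice_class_levels <- function() {
  c("not_lung", "only_bronchi", "top_front", "middle", "bottom_rear")
}

# in-plane pose: map unposed 0-based (row, col) to posed coordinates by
# rotating `rotation_deg` about the slice centre (positive = rotation of
# the spine->breastbone axis as reported by estimate_chest_frame) and
# then translating by shift_px
pose_point <- function(rc, rotation_deg, shift_px, shape) {
  ctr <- (shape - 1) / 2
  th <- rotation_deg * pi / 180
  # work in (x = col, y = -row) so positive angles match the chest-frame
  # angle convention (anterior axis toward +y)
  x <- rc[, 2] - ctr[2]
  y <- -(rc[, 1] - ctr[1])
  xp <- cos(th) * x - sin(th) * y
  yp <- sin(th) * x + cos(th) * y
  cbind(row = -yp + ctr[1] + shift_px[1], col = xp + ctr[2] + shift_px[2])
}

unpose_point <- function(rc, rotation_deg, shift_px, shape) {
  rc <- cbind(rc[, 1] - shift_px[1], rc[, 2] - shift_px[2])
  pose_point(rc, -rotation_deg, c(0, 0), shape)
}

#' Generate a synthetic thorax phantom with ground truth
#'
#' Builds a posed, noisy micro-CT stack of a mouse thorax: an elliptical
#' body of soft tissue containing two aerated lungs (the left lung
#' single-lobed and smaller, murine anatomy), a trachea branching into
#' the main bronchi, a sternum (anterior midline) and vertebral column
#' (posterior midline), surrounded by air. Disease transforms act on lung
#' voxels only: fibrosis replaces a fraction `0.6 * severity` of
#' parenchyma with dense spherical blobs (radius 3-8 voxels) drawn from
#' the soft-tissue intensity distribution, emphysema shifts the
#' parenchyma mean down by `250 * severity`, and LPS leaves densities
#' unchanged. Outcome covariates (Ashcroft score, mean linear intercept,
#' forced vital capacity) are simulated from severity.
#'
#' @param spec a [phantom_spec()].
#' @return A list with elements `stack` (an [image_stack()]) and `truth`
#'   (class `phantom_truth`: `lung_mask`, `airway_mask`, `bone_mask`,
#'   `fibrotic_mask`, per-slice `slice_classes`, per-slice
#'   `landmark_boxes`, the realized `pose`, `severity`, `disease` and
#'   simulated `covariates`).
#' @export
generate_phantom <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  with_seed(spec$rng_seed, generate_phantom_impl(spec))
}

generate_phantom_impl <- function(spec) {
  g <- phantom_geometry()
  nr <- spec$slice_shape[1]; nc <- spec$slice_shape[2]; nz <- spec$n_slices
  shape <- c(nr, nc)

  rot <- spec$rotation_deg %||% runif(1, -10, 10)
  shift <- spec$shift_px %||% (runif(2, -15, 15) * min(shape) / 512)

  # unposed coordinates of every pixel centre (same for all slices)
  ctr <- (shape - 1) / 2
  pr <- matrix(rep(0:(nr - 1), nc), nr, nc)
  pc <- matrix(rep(0:(nc - 1), each = nr), nr, nc)
  up <- unpose_point(cbind(as.vector(pr), as.vector(pc)), rot, shift, shape)
  ur <- matrix(up[, 1], nr, nc)  # unposed row coordinate of each pixel
  uc <- matrix(up[, 2], nr, nc)

  frow <- function(f) f * (nr - 1)   # fractional row -> 0-based coordinate
  fcol <- function(f) f * (nc - 1)
  rrad <- function(f) f * nr         # fractional length -> voxels (rows)
  crad <- function(f) f * nc

  in_ellipse <- function(row0, col0, a, b)
    ((ur - frow(row0)) / rrad(a))^2 + ((uc - fcol(col0)) / crad(b))^2 <= 1
  in_disc <- function(row0, col0, r)
    (ur - frow(row0))^2 + (uc - fcol(col0))^2 <= (rrad(r))^2

  body2d    <- in_ellipse(g$body$row, g$body$col, g$body$a, g$body$b)
  sternum2d <- in_disc(g$sternum$row, g$sternum$col, g$sternum$r)
  spine2d   <- in_disc(g$spine$row, g$spine$col, g$spine$r)
  bone2d    <- sternum2d | spine2d
  trachea2d <- in_disc(g$trachea$row, g$trachea$col, g$trachea$r)

  box_of <- function(mask) {
    if (!any(mask)) return(NULL)
    w <- which(mask, arr.ind = TRUE)
    # 0-based, half-open [r0, r1) x [c0, c1)
    c(min(w[, 1]) - 1L, min(w[, 2]) - 1L, max(w[, 1]), max(w[, 2]))
  }
  boxes <- list(breastbone = box_of(sternum2d), spine = box_of(spine2d))
  have_boxes <- !is.null(boxes$breastbone) && !is.null(boxes$spine)

  zf <- (seq_len(nz) - 0.5) / nz            # fractional z of each slice
  body_z <- zf >= g$body$z[1] & zf <= g$body$z[2]
  lung_zc <- mean(g$lung_z); lung_c <- diff(g$lung_z) / 2
  w <- (zf - lung_zc) / lung_c              # -1..1 across the lung span
  trachea_z <- zf >= g$trachea$z[1] & zf < g$trachea$z[2]
  bronchi_z <- zf >= g$bronchi$z[1] & zf <= g$bronchi$z[2]

  lung_mask <- array(FALSE, c(nr, nc, nz))
  airway_mask <- array(FALSE, c(nr, nc, nz))
  bone_mask <- array(FALSE, c(nr, nc, nz))

  lung2d_at <- function(z) {
    if (abs(w[z]) >= 1) return(NULL)
    s <- sqrt(1 - w[z]^2)
    rl <- g$lungs$right; ll <- g$lungs$left
    dr <- g$drift * w[z]
    in_ellipse(rl$row, rl$col - dr, rl$a * s, rl$b * s) |
      in_ellipse(ll$row, ll$col + dr, ll$a * s, ll$b * s)
  }
  airway2d_at <- function(z) {
    if (trachea_z[z]) return(trachea2d)
    if (!bronchi_z[z]) return(NULL)
    t <- (zf[z] - g$bronchi$z[1]) / diff(g$bronchi$z)
    r0 <- g$trachea$row + t * (g$bronchi$end_row - g$trachea$row)
    off <- t * g$bronchi$end_col_off
    in_disc(r0, g$trachea$col - off, g$bronchi$r) |
      in_disc(r0, g$trachea$col + off, g$bronchi$r)
  }

  for (z in seq_len(nz)) {
    if (!body_z[z]) next
    aw <- airway2d_at(z)
    lg <- lung2d_at(z)
    bn <- bone2d & body_z[z]
    if (!is.null(aw)) airway_mask[, , z] <- aw & !bn
    if (!is.null(lg)) {
      lg <- lg & !bn
      if (!is.null(aw)) lg <- lg & !aw
      lung_mask[, , z] <- lg
    }
    bone_mask[, , z] <- bn
  }

  # slice classes from lung extent: 30% top/front, 30% middle, 40%
  # bottom/rear of lung-bearing slices; pre-lung slices showing airway
  # are "only bronchi"
  lung_present <- apply(lung_mask, 3, any)
  airway_present <- apply(airway_mask, 3, any)
  classes <- rep("not_lung", nz)
  li <- which(lung_present)
  if (length(li)) {
    k <- length(li)
    n_top <- round(0.3 * k); n_mid <- round(0.3 * k)
    classes[li[seq_len(n_top)]] <- "top_front"
    classes[li[n_top + seq_len(n_mid)]] <- "middle"
    classes[li[(n_top + n_mid + 1):k]] <- "bottom_rear"
    pre <- seq_len(min(li) - 1)
    classes[pre[airway_present[pre]]] <- "only_bronchi"
  }
  classes <- factor(classes, levels = slice_class_levels())

  # fibrotic blob placement (fibrosis only): dense spheres replacing a
  # target fraction 0.6 * severity of lung voxels
  fib_mask <- NULL
  if (spec$disease == "fibrosis" && spec$severity > 0) {
    fib_mask <- array(FALSE, c(nr, nc, nz))
    n_lung <- sum(lung_mask)
    target <- round(0.6 * spec$severity * n_lung)
    placed <- 0L
    vol_r <- g$lungs$right$a * g$lungs$right$b
    p_right <- vol_r / (vol_r + g$lungs$left$a * g$lungs$left$b)
    guard <- 0L
    while (placed < target && guard < 100000L) {
      guard <- guard + 1L
      # uniform point in the chosen lung ellipsoid via unit-ball rejection
      repeat {
        ball <- runif(3, -1, 1)
        if (sum(ball^2) <= 1) break
      }
      lobe <- if (runif(1) < p_right) g$lungs$right else g$lungs$left
      sgn <- if (identical(lobe, g$lungs$right)) -1 else 1
      z0 <- lung_zc * nz + ball[3] * lung_c * nz
      wz <- ball[3]
      u0 <- c(frow(lobe$row) + ball[1] * rrad(lobe$a),
              fcol(lobe$col + sgn * g$drift * wz) + ball[2] * crad(lobe$b))
      p0 <- pose_point(matrix(u0, 1), rot, shift, shape)
      rad <- runif(1, 3, 8)
      zlo <- max(1L, ceiling(z0 - rad + 0.5))
      zhi <- min(nz, floor(z0 + rad + 0.5))
      if (zlo > zhi) next
      rlo <- max(1L, floor(p0[1] - rad)); rhi <- min(nr, ceiling(p0[1] + rad) + 1L)
      clo <- max(1L, floor(p0[2] - rad)); chi <- min(nc, ceiling(p0[2] + rad) + 1L)
      if (rlo > rhi || clo > chi) next
      rr <- rlo:rhi; cc <- clo:chi
      d2 <- outer((rr - 1 - p0[1])^2, (cc - 1 - p0[2])^2, `+`)
      for (z in zlo:zhi) {
        rz2 <- rad^2 - ((z - 0.5) - z0)^2
        if (rz2 <= 0) next
        sub <- d2 <= rz2 & lung_mask[rr, cc, z] & !fib_mask[rr, cc, z]
        nnew <- sum(sub)
        if (nnew) {
          fm <- fib_mask[rr, cc, z]
          fm[sub] <- TRUE
          fib_mask[rr, cc, z] <- fm
          placed <- placed + nnew
        }
      }
    }
  }

  # intensity pass: one N(0,1) draw per voxel, scaled by tissue class;
  # fibrotic voxels reuse the same draw around the dense-tissue mean so a
  # zero-severity phantom is voxelwise identical to control
  mu <- g$mu; sdv <- g$sd
  par_mu <- mu[["parenchyma"]] -
    if (spec$disease == "emphysema") 250 * spec$severity else 0
  mu_vec <- c(mu[["air"]], par_mu, mu[["airway"]], mu[["soft"]], mu[["bone"]])
  sd_vec <- c(sdv[["air"]], sdv[["parenchyma"]], sdv[["airway"]],
              sdv[["soft"]], sdv[["bone"]])
  voxels <- array(0L, c(nr, nc, nz))
  npx <- nr * nc
  for (z in seq_len(nz)) {
    cls <- rep(1L, npx)
    if (body_z[z]) {
      cls[body2d] <- 4L
      lg <- lung_mask[, , z]; aw <- airway_mask[, , z]; bn <- bone_mask[, , z]
      cls[lg] <- 2L
      cls[aw] <- 3L
      cls[bn] <- 5L
    }
    eps <- rnorm(npx)
    ii <- mu_vec[cls] + sd_vec[cls] * eps
    if (!is.null(fib_mask)) {
      fb <- as.vector(fib_mask[, , z])
      if (any(fb))
        ii[fb] <- mu[["fibrotic"]] + sdv[["fibrotic"]] * eps[fb]
    }
    voxels[, , z] <- as.integer(clamp(round_half_up(ii), 0, 65535))
  }

  landmark_boxes <- vector("list", nz)
  if (have_boxes)
    for (z in which(body_z))
      landmark_boxes[[z]] <- structure(boxes, class = "landmark_boxes")

  sev <- spec$severity
  covariates <- list(
    ashcroft_score = clamp(round(7 * (if (spec$disease == "fibrosis") sev else 0)) +
                             rnorm(1, 0, 0.5), 0, 8),
    mli_um = 40 + 60 * (if (spec$disease == "emphysema") sev else 0) +
      rnorm(1, 0, 3),
    fvc_ml = 1.2 - 0.6 * sev + rnorm(1, 0, 0.05))

  truth <- structure(list(
    lung_mask = lung_mask, airway_mask = airway_mask, bone_mask = bone_mask,
    fibrotic_mask = fib_mask, slice_classes = classes,
    landmark_boxes = landmark_boxes,
    pose = list(rotation_deg = rot, shift_px = shift),
    severity = sev, disease = spec$disease, covariates = covariates),
    class = "phantom_truth")

  list(stack = image_stack(voxels, rep(spec$voxel_size_mm, 3)),
       truth = truth)
}

#' Generate a reproducible phantom cohort
#'
#' One phantom per animal with per-animal seeds derived from
#' `master_seed`. Diseased arms receive severities evenly spaced over
#' `severity_range`; control arms have severity 0.
#'
#' @param n_per_arm animals per disease arm (>= 1).
#' @param diseases character vector of arms.
#' @param severity_range length-2 numeric range for diseased arms.
#' @param master_seed integer master seed.
#' @param ... further arguments passed to [phantom_spec()] (e.g.
#'   `n_slices`, `slice_shape`).
#' @return A list of per-animal lists: `animal_id`, `stack`, `truth`,
#'   `spec`.
#' @export
generate_cohort <- function(n_per_arm, diseases = c("control", "fibrosis"),
                            severity_range = c(0.2, 1), master_seed = 1L,
                            ...) {
  if (n_per_arm < 1) stop("n_per_arm must be >= 1")
  if (!length(diseases)) stop("diseases must be a nonempty list")
  out <- list()
  k <- 0L
  for (dis in diseases) {
    sev <- if (dis == "control") rep(0, n_per_arm)
           else if (n_per_arm == 1) mean(severity_range)
           else seq(severity_range[1], severity_range[2],
                    length.out = n_per_arm)
    for (i in seq_len(n_per_arm)) {
      k <- k + 1L
      seed <- (as.integer(master_seed) + 104729L * k) %% 2147483647L
      spec <- phantom_spec(disease = dis, severity = sev[i],
                           rng_seed = seed, ...)
      ph <- generate_phantom(spec)
      out[[k]] <- list(animal_id = sprintf("%s_%02d", dis, i),
                       stack = ph$stack, truth = ph$truth, spec = spec)
    }
  }
  out
}
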
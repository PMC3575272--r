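#' Subject specification
#'
#' Height and total body mass of the modelled subject. The default values are
#' the study-population means used throughout the package examples
#' (1.78 m, 86 kg).
#'
#' @param height_m standing height in metres (> 0)
#' @param mass_kg total body mass in kilograms (> 0)
#' @return an object of class `subject_spec`
#' @export
subject_spec <- function(height_m = 1.78, mass_kg = 86) {
  if (!is.numeric(height_m) || length(height_m) != 1 || !is.finite(height_m) ||
      height_m <= 0) {
    stop("`height_m` must be a single positive number", call. = FALSE)
  }
  if (!is.numeric(mass_kg) || length(mass_kg) != 1 || !is.finite(mass_kg) ||
      mass_kg <= 0) {
    stop("`mass_kg` must be a single positive number", call. = FALSE)
  }
  structure(list(height_m = height_m, mass_kg = mass_kg),
            class = "subject_spec")
}

#' Default anthropometric fraction table
#'
#' Segment mass, length, and centre-of-mass fractions for the two-link
#' (legs + head-arms-trunk) reduction of the body, assembled from standard
#' segment tables: the legs link lumps both thighs, shanks and feet
#' (2 x (0.100 + 0.0465 + 0.0145) of body mass) and spans ground to greater
#' trochanter (0.530 of height); the torso link is the head-arms-trunk
#' segment. These are documented stand-in defaults, fully overridable; the
#' model treats the resulting `body_params` as given.
#'
#' `com_fraction` is the centre-of-mass distance from the link's proximal
#' joint (ankle for the legs, hip for the torso) as a fraction of link
#' length. `shape` selects the solid used for the inertia tensor; shape
#' dimensions are fractions of link length.
#'
#' @return a named list with one entry per link (`legs`, `torso`)
#' @export
default_fraction_table <- function() {
  list(
    legs = list(
      mass_fraction = 0.322,
      length_fraction = 0.530,
      com_fraction = 0.56,
      shape = "cylinder",
      # radius as a fraction of link length (both legs lumped in one solid)
      shape_dims = c(radius_fraction = 0.13)
    ),
    torso = list(
      mass_fraction = 0.678,
      length_fraction = 0.470,
      com_fraction = 0.35,
      shape = "ellipsoid",
      # semi-axes (sagittal depth, coronal width, vertical) / link length
      shape_dims = c(a_fraction = 0.13, b_fraction = 0.20, c_fraction = 0.50)
    )
  )
}

#' Inertia tensor of a homogeneous solid
#'
#' Closed-form principal inertia tensor about the centre of mass for the two
#' solids used to approximate body links: a solid circular cylinder with its
#' axis along z, and a solid ellipsoid with semi-axes (a, b, c) along
#' (x, y, z).
#'
#' @param shape `"cylinder"` (dimensions: `radius`, `length`) or
#'   `"ellipsoid"` (dimensions: `a`, `b`, `c` semi-axes)
#' @param mass_kg solid mass (kg, > 0)
#' @param dims named numeric vector of dimensions in metres
#' @return 3x3 diagonal inertia matrix (kg m^2), axes (x, y, z)
#' @export
solid_inertia <- function(shape, mass_kg, dims) {
  if (!is.numeric(mass_kg) || mass_kg <= 0) {
    stop("`mass_kg` must be positive", call. = FALSE)
  }
  if (any(dims < 0)) stop("dimensions must be non-negative", call. = FALSE)
  shape <- match.arg(shape, c("cylinder", "ellipsoid"))
  if (shape == "cylinder") {
    r <- dims[["radius"]]
    L <- dims[["length"]]
    It <- mass_kg * (3 * r^2 + L^2) / 12 # transverse
    Ia <- mass_kg * r^2 / 2              # axial (z)
    diag(c(It, It, Ia))
  } else {
    a <- dims[["a"]]
    b <- dims[["b"]]
    c_ <- dims[["c"]]
    diag(mass_kg / 5 * c(b^2 + c_^2, a^2 + c_^2, a^2 + b^2))
  }
}

#' Derive two-link body parameters from subject height and mass
#'
#' Multiplies total mass and height by the fraction table to obtain link
#' masses, lengths and centre-of-mass offsets, and evaluates the closed-form
#' solid inertia tensors (cylinder legs, ellipsoid head-arms-trunk).
#'
#' @param subject a [subject_spec()]
#' @param fractions fraction table as from [default_fraction_table()]
#' @param ankle_offset_m vertical offset of the ankle above the platform (m)
#' @return an object of class `body_params` with elements `legs` and `torso`
#'   (each: `mass_kg`, `length_m`, `com_m`, `inertia`), `ankle_offset_m`,
#'   and `g` (9.81 m/s^2)
#' @export
derive_body_params <- function(subject = subject_spec(),
                               fractions = default_fraction_table(),
                               ankle_offset_m = 0) {
  stopifnot(inherits(subject, "subject_spec"))
  H <- subject$height_m
  M <- subject$mass_kg

  link <- function(fr) {
    m <- M * fr$mass_fraction
    L <- H * fr$length_fraction
    com <- L * fr$com_fraction
    inertia <- if (identical(fr$shape, "cylinder")) {
      solid_inertia("cylinder", max(m, .Machine$double.xmin),
                    c(radius = L * fr$shape_dims[["radius_fraction"]],
                      length = L))
    } else if (identical(fr$shape, "ellipsoid")) {
      solid_inertia("ellipsoid", max(m, .Machine$double.xmin),
                    c(a = L * fr$shape_dims[["a_fraction"]],
                      b = L * fr$shape_dims[["b_fraction"]],
                      c = L * fr$shape_dims[["c_fraction"]]))
    } else {
      stop("unknown shape: ", fr$shape, call. = FALSE)
    }
    if (m == 0) inertia <- diag(0, 3)
    list(mass_kg = m, length_m = L, com_m = com, inertia = inertia)
  }

  bp <- structure(
    list(legs = link(fractions$legs),
         torso = link(fractions$torso),
         ankle_offset_m = ankle_offset_m,
         g = 9.81),
    class = "body_params"
  )
  validate_body_params(bp, total_mass = M)
  bp
}

#' Validate body parameters
#'
#' Checks the `body_params` invariants: non-negative masses, lengths and
#' centre-of-mass offsets; symmetric positive semi-definite inertia tensors;
#' link masses not exceeding `total_mass` when supplied. Zero-mass or
#' zero-length links are rejected (the pendulum would be degenerate).
#'
#' @param bp a `body_params` object
#' @param total_mass optional total body mass (kg) for the mass-sum check
#' @return `bp`, invisibly; errors on violation
#' @export
validate_body_params <- function(bp, total_mass = NULL) {
  stopifnot(inherits(bp, "body_params"))
  for (nm in c("legs", "torso")) {
    lk <- bp[[nm]]
    if (!all(is.finite(c(lk$mass_kg, lk$length_m, lk$com_m))) ||
        lk$mass_kg <= 0 || lk$length_m <= 0 || lk$com_m < 0) {
      stop(sprintf("link '%s': mass and length must be positive, com >= 0", nm),
           call. = FALSE)
    }
    if (lk$com_m > lk$length_m) {
      stop(sprintf("link '%s': centre of mass lies beyond the link", nm),
           call. = FALSE)
    }
    Im <- lk$inertia
    if (!isTRUE(all.equal(Im, t(Im))) || any(eigen(Im, symmetric = TRUE,
                                                   only.values = TRUE)$values < -1e-12)) {
      stop(sprintf("link '%s': inertia tensor must be symmetric PSD", nm),
           call. = FALSE)
    }
  }
  if (!is.null(total_mass) &&
      bp$legs$mass_kg + bp$torso$mass_kg > total_mass + 1e-9) {
    stop("link masses exceed total body mass", call. = FALSE)
  }
  invisible(bp)
}

#' @export
print.body_params <- function(x, ...) {
  cat("Two-link body parameters\n")
  for (nm in c("legs", "torso")) {
    lk <- x[[nm]]
    cat(sprintf("  %-5s  m = %6.2f kg  L = %5.3f m  com = %5.3f m  I = (%.3f, %.3f, %.3f) kg m^2\n",
                nm, lk$mass_kg, lk$length_m, lk$com_m,
                lk$inertia[1, 1], lk$inertia[2, 2], lk$inertia[3, 3]))
  }
  invisible(x)
}

# pack into the flat numeric vector the compiled core expects
.pack_params <- function(bp) {
  c(bp$legs$mass_kg, bp$torso$mass_kg,
    bp$legs$length_m, bp$legs$com_m, bp$torso$com_m,
    bp$legs$inertia[1, 1], bp$legs$inertia[2, 2], bp$legs$inertia[3, 3],
    bp$torso$inertia[1, 1], bp$torso$inertia[2, 2], bp$torso$inertia[3, 3],
    bp$g)
}
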
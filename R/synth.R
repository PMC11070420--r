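#' Parameters for the synthetic capillary-network generator
#'
#' Bundles the knobs of the synthetic en face OCTA image generator. The
#' generator places capillary junctions by Poisson-disc sampling, connects
#' them with a planar proximity (Gabriel) graph, optionally removes edges to
#' emulate capillary dropout, and rasterises the surviving centrelines with a
#' Gaussian intensity profile plus multiplicative speckle.
#'
#' @param image_size Image side length in pixels.
#' @param pixel_pitch_um Lateral sampling in micrometres per pixel. The
#'   default 5.7 matches 15x15 degree (~3x3 mm) macular scans sampled on a
#'   512 grid.
#' @param mean_capillary_spacing_px Poisson-disc radius, i.e. the minimum
#'   (and roughly the mean) spacing between capillary junctions, in pixels.
#'   The default 12 px is about 68 um, a typical macular intercapillary
#'   scale.
#' @param vessel_sigma_px Standard deviation of the Gaussian line profile
#'   used to rasterise vessel centrelines, in pixels. Ground-truth masks
#'   cover pixels within this distance of an alive centreline.
#' @param noise_level Coefficient of variation of the multiplicative gamma
#'   speckle applied to the rendered image; 0 disables noise.
#' @param dropout_prob Per-edge probability that a capillary segment is
#'   removed, the severity knob standing in for glaucomatous non-perfusion.
#' @param seed Integer seed; every generator output is a pure function of
#'   the seed and these parameters.
#' @param bit_depth Output quantisation, 8 (default) or 16 bits.
#' @param clustered_dropout If `TRUE`, dropout probability is concentrated
#'   around a random focus instead of being spatially uniform (off by
#'   default; diffuse loss is the default disease model).
#'
#' @return A list of class `synth_params`.
#' @export
#' @examples
#' p <- synth_params(image_size = 128, seed = 7)
#' g <- generate_vessel_graph(p)
#' nrow(g$nodes)
synth_params <- function(image_size = 512,
                         pixel_pitch_um = 5.7,
                         mean_capillary_spacing_px = 12,
                         vessel_sigma_px = 1.0,
                         noise_level = 0.4,
                         dropout_prob = 0,
                         seed = 1L,
                         bit_depth = 8,
                         clustered_dropout = FALSE) {
  stopifnot(
    image_size > 0, pixel_pitch_um > 0,
    mean_capillary_spacing_px > 0, vessel_sigma_px > 0,
    noise_level >= 0, dropout_prob >= 0, dropout_prob <= 1,
    bit_depth %in% c(8, 16)
  )
  structure(list(
    image_size = as.integer(image_size),
    pixel_pitch_um = pixel_pitch_um,
    mean_capillary_spacing_px = mean_capillary_spacing_px,
    vessel_sigma_px = vessel_sigma_px,
    noise_level = noise_level,
    dropout_prob = dropout_prob,
    seed = as.integer(seed),
    bit_depth = as.integer(bit_depth),
    clustered_dropout = isTRUE(clustered_dropout)
  ), class = "synth_params")
}

#' Generate a synthetic capillary graph
#'
#' Poisson-disc sampling (Bridson's algorithm) places capillary junctions at
#' a minimum spacing of `mean_capillary_spacing_px`; junctions are then
#' connected by the Gabriel graph (a planar proximity graph that contains
#' the Euclidean minimum spanning tree, hence is connected) with edges
#' longer than twice the mean spacing pruned. The resulting polygonal
#' lacunae resemble the intercapillary spaces of en face OCTA projections.
#'
#' @param params A [synth_params()] object.
#' @return A list of class `vessel_graph` with `nodes` (n x 2 matrix of
#'   row/column pixel coordinates, sub-pixel precision), `edges` (E x 2
#'   matrix of node indices) and `edge_alive` (logical, all `TRUE`).
#' @export
generate_vessel_graph <- function(params) {
  stopifnot(inherits(params, "synth_params"))
  nodes <- with_seed(params$seed, {
    .poisson_disc(params$image_size, params$mean_capillary_spacing_px, 30L)
  })
  if (nrow(nodes) < 4) stop("degenerate geometry", call. = FALSE)
  edges <- .gabriel_edges(nodes, 2 * params$mean_capillary_spacing_px)
  structure(list(
    nodes = nodes,
    edges = edges,
    edge_alive = rep(TRUE, nrow(edges)),
    params = params
  ), class = "vessel_graph")
}

#' Remove capillary segments to emulate non-perfusion
#'
#' Marks each edge dead independently with probability `dropout_prob`
#' (i.i.d. by default). With `clustered_dropout` in the graph's parameters,
#' the per-edge probability is modulated by a Gaussian focus centred on a
#' random node so that loss concentrates in one neighbourhood while the
#' mean dropout rate is preserved.
#'
#' @param graph A `vessel_graph`.
#' @param dropout_prob Per-edge removal probability in \[0, 1\].
#' @param seed Integer seed for the dropout draw.
#' @return The graph with `edge_alive` updated; nodes and edges unchanged.
#' @export
apply_dropout <- function(graph, dropout_prob, seed) {
  stopifnot(inherits(graph, "vessel_graph"),
            dropout_prob >= 0, dropout_prob <= 1)
  ne <- nrow(graph$edges)
  if (ne == 0L) return(graph)
  alive <- with_seed(seed, {
    if (isTRUE(graph$params$clustered_dropout) && dropout_prob > 0) {
      centre <- graph$nodes[sample.int(nrow(graph$nodes), 1L), ]
      mid_r <- (graph$nodes[graph$edges[, 1], 1] +
                  graph$nodes[graph$edges[, 2], 1]) / 2
      mid_c <- (graph$nodes[graph$edges[, 1], 2] +
                  graph$nodes[graph$edges[, 2], 2]) / 2
      s <- graph$params$image_size / 4
      w <- exp(-((mid_r - centre[1])^2 + (mid_c - centre[2])^2) / (2 * s^2))
      p <- pmin(1, dropout_prob * w * ne / sum(w))
      runif(ne) >= p
    } else {
      runif(ne) >= dropout_prob
    }
  })
  if (dropout_prob == 0) alive <- rep(TRUE, ne)
  if (dropout_prob == 1) alive <- rep(FALSE, ne)
  graph$edge_alive <- graph$edge_alive & alive
  graph
}

#' Rasterise a capillary graph into an en face image and truth mask
#'
#' Alive edges are rendered as bright anti-aliased curves: each pixel takes
#' intensity `exp(-d^2 / (2 sigma^2))` of its distance `d` to the nearest
#' alive centreline, on top of a dim background floor. Multiplicative gamma
#' speckle with coefficient of variation `noise_level` emulates OCTA speckle,
#' and the result is quantised to the configured bit depth. The ground-truth
#' mask contains exactly the pixels within `vessel_sigma_px` of an alive
#' centreline.
#'
#' @param graph A `vessel_graph` (after any dropout).
#' @param params A [synth_params()] object; defaults to the graph's own.
#' @return A list with `image` (numeric matrix in \[0, 1\]) and `mask`
#'   (logical matrix), both carrying a `pixel_pitch_um` attribute.
#' @export
render_image <- function(graph, params = graph$params) {
  stopifnot(inherits(graph, "vessel_graph"), inherits(params, "synth_params"))
  n <- params$image_size
  sig <- params$vessel_sigma_px
  keep <- which(graph$edge_alive)
  if (length(keep) > 0) {
    a <- graph$nodes[graph$edges[keep, 1], , drop = FALSE]
    b <- graph$nodes[graph$edges[keep, 2], , drop = FALSE]
    cap <- max(4 * sig, sig + 1)
    d <- .segment_distance_field(n, n, a[, 1], a[, 2], b[, 1], b[, 2], cap)
  } else {
    d <- matrix(Inf, n, n)
  }
  profile <- ifelse(is.finite(d), exp(-d^2 / (2 * sig^2)), 0)
  bg <- 0.08
  img <- bg + (1 - bg) * profile
  if (params$noise_level > 0) {
    k <- 1 / params$noise_level^2
    img <- with_seed(params$seed + 1L,
                     img * rgamma(length(img), shape = k, rate = k))
    dim(img) <- c(n, n)
  }
  levels <- 2^params$bit_depth - 1
  img <- round(clamp01(img) * levels) / levels
  mask <- is.finite(d) & d <= sig
  list(image = set_pitch(img, params$pixel_pitch_um),
       mask = set_pitch(mask, params$pixel_pitch_um))
}

#' Generate a two-class synthetic cohort on disk
#'
#' Renders `n_control + n_case` synthetic eyes, writes images and
#' ground-truth masks as grayscale PNGs under `out_dir`, and returns a
#' cohort manifest. Eyes are grouped into patients with on average ~1.4
#' eyes per patient (a patient contributes a second eye with probability
#' 0.4), mirroring clinical cohorts where both eyes of some subjects are
#' scanned, so that patient-grouped splitting is exercised downstream.
#'
#' @param n_control,n_case Number of control and case (dropout-degraded)
#'   eyes; both at least 1.
#' @param params_control,params_case Generator parameters per class; the
#'   per-eye `seed` and `dropout_prob` fields are taken from these.
#' @param seed Master seed; eye-level seeds are drawn from it, so the whole
#'   cohort (including the manifest CSV bytes) is reproducible.
#' @param out_dir Output directory, created if missing.
#' @param plexus Plexus tag recorded in the manifest.
#' @return A tibble manifest with columns `image_id`, `patient_id`, `eye`,
#'   `plexus`, `label`, `image_path`, `mask_path`; also written as
#'   `manifest.csv` in `out_dir`.
#' @export
#' @examples
#' \donttest{
#' dir <- file.path(tempdir(), "cohort-demo")
#' man <- generate_cohort(3, 3,
#'   params_control = synth_params(image_size = 128),
#'   params_case = synth_params(image_size = 128, dropout_prob = 0.35),
#'   seed = 1, out_dir = dir)
#' man
#' }
generate_cohort <- function(n_control, n_case,
                            params_control = synth_params(),
                            params_case = synth_params(dropout_prob = 0.35),
                            seed = 1L, out_dir, plexus = "SVP") {
  stopifnot(n_control >= 1, n_case >= 1,
            inherits(params_control, "synth_params"),
            inherits(params_case, "synth_params"))
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok || !dir.exists(out_dir))
      stop("cannot create output directory: ", out_dir, call. = FALSE)
  }
  plan <- with_seed(seed, {
    assign_eyes <- function(n, prefix) {
      pid <- character(n); eye <- character(n)
      i <- 1L; p <- 0L
      while (i <= n) {
        p <- p + 1L
        id <- sprintf("%s%03d", prefix, p)
        two <- (runif(1) < 0.4) && (i + 1L <= n)
        pid[i] <- id; eye[i] <- "OD"; i <- i + 1L
        if (two) { pid[i] <- id; eye[i] <- "OS"; i <- i + 1L }
      }
      list(pid = pid, eye = eye)
    }
    ctrl <- assign_eyes(n_control, "C")
    case <- assign_eyes(n_case, "G")
    list(ctrl = ctrl, case = case,
         eye_seeds = sample.int(.Machine$integer.max - 2L,
                                n_control + n_case))
  })
  pid <- c(plan$ctrl$pid, plan$case$pid)
  eye <- c(plan$ctrl$eye, plan$case$eye)
  label <- rep(c("control", "glaucoma"), c(n_control, n_case))
  n_total <- n_control + n_case
  rows <- vector("list", n_total)
  for (i in seq_len(n_total)) {
    p <- if (label[i] == "control") params_control else params_case
    p$seed <- plan$eye_seeds[i]
    g <- generate_vessel_graph(p)
    g <- apply_dropout(g, p$dropout_prob, seed = p$seed + 2L)
    r <- render_image(g, p)
    image_id <- sprintf("%s_%s", pid[i], eye[i])
    ext <- if (p$bit_depth == 16) ".tif" else ".png"
    image_path <- file.path(out_dir, paste0(image_id, ext))
    mask_path <- file.path(out_dir, paste0(image_id, "_mask.png"))
    write_image(r$image, image_path, bit_depth = p$bit_depth)
    write_mask(r$mask, mask_path)
    rows[[i]] <- tibble::tibble(
      image_id = image_id, patient_id = pid[i], eye = eye[i],
      plexus = plexus, label = label[i],
      image_path = image_path, mask_path = mask_path
    )
  }
  manifest <- dplyr::bind_rows(rows)
  readr::write_csv(manifest, file.path(out_dir, "manifest.csv"))
  manifest
}
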
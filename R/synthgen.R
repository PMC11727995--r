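# run code with a locally seeded RNG, restoring global RNG state afterwards
with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Synthetic wound-scene parameters
#'
#' Describes one synthetic photograph of a stapled abdominal incision:
#' a noisy skin-tone background, a linear incision, metallic staples
#' crossing it, peri-incisional erythema whose amplitude scales with
#' `erythema_intensity` and decays with distance from the incision, and
#' optional confounders (colored antiseptic stain patches, a dressing edge
#' at the image border). Defaults mirror the imaging setting the pipeline is
#' built for: at least 500 x 500 px uploads of a stapled wound.
#'
#' @param image_size integer `(H, W)`, at least `(500, 500)` by default.
#' @param skin_rgb base skin colour (RGB in \[0, 1\]).
#' @param skin_noise_sd per-pixel Gaussian texture SD.
#' @param incision list: `orientation_deg` (`NULL` = drawn uniformly in
#'   \[0, 180)), `length_px`, `width_px`, `color`.
#' @param n_staples number of staples (0 allowed).
#' @param staple_spacing_px,staple_length_px,staple_width_px staple layout.
#' @param staple_brightness metallic staple gray level.
#' @param erythema_intensity severity of peri-wound redness in \[0, 1\]; the
#'   image is labelled infected when it exceeds `label_cutoff`.
#' @param erythema_halfwidth_px Gaussian decay scale of the red shift
#'   perpendicular to the incision.
#' @param erythema_color the erythema target colour the skin is blended
#'   toward.
#' @param artifacts list: `stain_probability`, `stain_color`,
#'   `dressing_probability`.
#' @param label_cutoff generative infection cutoff on `erythema_intensity`.
#' @param seed integer seed; identical params + seed give byte-identical
#'   output.
#' @return A `wound_scene_params` list.
#' @export
wound_scene_params <- function(image_size = c(512, 512),
                               skin_rgb = c(0.80, 0.62, 0.45),
                               skin_noise_sd = 0.02,
                               incision = list(orientation_deg = NULL,
                                               length_px = 300, width_px = 2,
                                               color = c(0.45, 0.15, 0.15)),
                               n_staples = 6,
                               staple_spacing_px = 40,
                               staple_length_px = 25,
                               staple_width_px = 3,
                               staple_brightness = 0.92,
                               erythema_intensity = 0.2,
                               erythema_halfwidth_px = 30,
                               erythema_color = c(0.70, 0.15, 0.20),
                               artifacts = list(stain_probability = 0.15,
                                                stain_color = c(0.60, 0.20, 0.18),
                                                dressing_probability = 0.10),
                               label_cutoff = 0.5,
                               seed = 1) {
  stopifnot(length(image_size) == 2, all(image_size >= 1),
            erythema_intensity >= 0, erythema_intensity <= 1,
            n_staples >= 0,
            artifacts$stain_probability >= 0, artifacts$stain_probability <= 1,
            artifacts$dressing_probability >= 0,
            artifacts$dressing_probability <= 1)
  inc_default <- list(orientation_deg = NULL, length_px = 300, width_px = 2,
                      color = c(0.45, 0.15, 0.15))
  incision <- modifyList(inc_default, incision)
  structure(list(image_size = as.integer(image_size), skin_rgb = skin_rgb,
                 skin_noise_sd = skin_noise_sd, incision = incision,
                 n_staples = as.integer(n_staples),
                 staple_spacing_px = staple_spacing_px,
                 staple_length_px = staple_length_px,
                 staple_width_px = staple_width_px,
                 staple_brightness = staple_brightness,
                 erythema_intensity = erythema_intensity,
                 erythema_halfwidth_px = erythema_halfwidth_px,
                 erythema_color = erythema_color,
                 artifacts = artifacts,
                 label_cutoff = label_cutoff,
                 seed = as.integer(seed)),
            class = "wound_scene_params")
}

blend_channels <- function(px, where, alpha, color) {
  for (k in 1:3) {
    ch <- px[, , k]
    ch[where] <- (1 - alpha[where]) * ch[where] + alpha[where] * color[k]
    px[, , k] <- ch
  }
  px
}

#' Generate one synthetic wound photograph with ground truth
#'
#' Deterministic given `params` (including its seed). Scene layers, in draw
#' order: textured skin, peri-incisional erythema, the incision line,
#' antiseptic stains, a dressing edge, and finally the staples (staples sit
#' on top of everything, as they do physically).
#'
#' @param params a [wound_scene_params()].
#' @return A list `image` (a [wound_image()]) and `truth`: `staple_mask`,
#'   `staple_centroids`, `staple_orientation_deg`, `incision_axis`
#'   (`point` + unit `direction`), `erythema_intensity`, `infected_label`,
#'   `has_stain`, `has_dressing`.
#' @export
#' @examples
#' sc <- generate_wound_image(wound_scene_params(seed = 42))
#' sc$truth$infected_label
generate_wound_image <- function(params = wound_scene_params()) {
  stopifnot(inherits(params, "wound_scene_params"))
  with_local_seed(params$seed, {
    h <- params$image_size[1]; w <- params$image_size[2]
    theta <- params$incision$orientation_deg
    if (is.null(theta)) theta <- runif(1, 0, 180)
    th <- theta * pi / 180
    d <- c(sin(th), cos(th))                 # (d_row, d_col), angle from col axis
    nz <- which(abs(d) > 1e-12)[1]
    if (d[nz] < 0) d <- -d
    ctr <- c((h + 1) / 2, (w + 1) / 2)

    rr <- matrix(seq_len(h), h, w) - ctr[1]
    cc <- matrix(seq_len(w), h, w, byrow = TRUE) - ctr[2]
    along <- rr * d[1] + cc * d[2]
    perp <- abs(rr * d[2] - cc * d[1])

    # skin with Gaussian texture
    px <- array(0, c(h, w, 3))
    for (k in 1:3)
      px[, , k] <- params$skin_rgb[k] + rnorm(h * w, 0, params$skin_noise_sd)

    # erythema: red shift decaying with perpendicular distance, tapering
    # past the incision ends
    if (params$erythema_intensity > 0) {
      hw <- params$erythema_halfwidth_px
      overhang <- pmax(0, abs(along) - params$incision$length_px / 2)
      alpha <- params$erythema_intensity *
        exp(-0.5 * (perp / hw)^2) * exp(-0.5 * (overhang / hw)^2)
      px <- blend_channels(px, alpha > 0.005, alpha, params$erythema_color)
    }

    # incision line
    inc <- perp <= params$incision$width_px / 2 &
      abs(along) <= params$incision$length_px / 2
    alpha_inc <- matrix(0, h, w); alpha_inc[inc] <- 0.85
    px <- blend_channels(px, inc, alpha_inc, params$incision$color)

    # antiseptic stain patches (translucent, drawn under the staples)
    has_stain <- runif(1) < params$artifacts$stain_probability
    if (has_stain) {
      n_patch <- sample(1:2, 1)
      for (i in seq_len(n_patch)) {
        pc <- c(runif(1, 0.2 * h, 0.8 * h), runif(1, 0.2 * w, 0.8 * w))
        rad <- runif(2, 30, 70)
        ang <- runif(1, 0, pi)
        u <- (matrix(seq_len(h), h, w) - pc[1]) * cos(ang) +
          (matrix(seq_len(w), h, w, byrow = TRUE) - pc[2]) * sin(ang)
        v <- -(matrix(seq_len(h), h, w) - pc[1]) * sin(ang) +
          (matrix(seq_len(w), h, w, byrow = TRUE) - pc[2]) * cos(ang)
        inside <- (u / rad[1])^2 + (v / rad[2])^2 <= 1
        alpha_st <- matrix(0, h, w); alpha_st[inside] <- 0.5
        px <- blend_channels(px, inside, alpha_st, params$artifacts$stain_color)
      }
    }

    # dressing edge: bright pad anchored at a random image border
    has_dressing <- runif(1) < params$artifacts$dressing_probability
    if (has_dressing) {
      side <- sample(1:4, 1)
      depth <- round(runif(1, 40, 100))
      dr_mask <- matrix(FALSE, h, w)
      if (side == 1) dr_mask[seq_len(depth), ] <- TRUE
      if (side == 2) dr_mask[(h - depth + 1):h, ] <- TRUE
      if (side == 3) dr_mask[, seq_len(depth)] <- TRUE
      if (side == 4) dr_mask[, (w - depth + 1):w] <- TRUE
      alpha_dr <- matrix(0, h, w); alpha_dr[dr_mask] <- 0.9
      px <- blend_channels(px, dr_mask, alpha_dr, c(0.96, 0.96, 0.93))
    }

    # staples: bright bars perpendicular to the incision
    staple_mask <- matrix(FALSE, h, w)
    centroids <- NULL
    if (params$n_staples > 0) {
      offs <- (seq_len(params$n_staples) - (params$n_staples + 1) / 2) *
        params$staple_spacing_px
      centroids <- cbind(ctr[1] + offs * d[1], ctr[2] + offs * d[2])
      reach <- params$staple_length_px / 2 + params$staple_width_px
      if (any(centroids[, 1] < 1 + reach | centroids[, 1] > h - reach |
              centroids[, 2] < 1 + reach | centroids[, 2] > w - reach))
        stop("staples would fall outside the image")
      for (i in seq_len(params$n_staples)) {
        srr <- rr + ctr[1] - centroids[i, 1]
        scc <- cc + ctr[2] - centroids[i, 2]
        s_along <- srr * d[1] + scc * d[2]          # along incision
        s_perp <- srr * d[2] - scc * d[1]           # along the staple bar
        bar <- abs(s_perp) <= params$staple_length_px / 2 &
          abs(s_along) <= params$staple_width_px / 2
        staple_mask <- staple_mask | bar
        g <- params$staple_brightness + runif(1, -0.015, 0.015)
        for (k in 1:3) { chn <- px[, , k]; chn[bar] <- g; px[, , k] <- chn }
      }
    }

    px[px < 0] <- 0; px[px > 1] <- 1
    img <- wound_image(px, source_id = sprintf("synth-%d", params$seed),
                       capture_tag = "synthetic", warn_undersized = FALSE)
    list(image = img,
         truth = list(staple_mask = staple_mask,
                      staple_centroids = centroids,
                      staple_orientation_deg = (theta + 90) %% 180,
                      incision_axis = list(point = ctr, direction = d),
                      incision_orientation_deg = theta %% 180,
                      erythema_intensity = params$erythema_intensity,
                      infected_label = as.integer(params$erythema_intensity >
                                                    params$label_cutoff),
                      has_stain = has_stain,
                      has_dressing = has_dressing))
  })
}

#' Generate a synthetic study cohort
#'
#' Emulates the study structure: patients photograph their wound on
#' post-operative days 3 and 10, each visit pairing an image with a
#' completed symptom questionnaire. Infection status is drawn per patient as
#' Bernoulli(`prevalence`); infected patients receive high erythema
#' intensities and elevated symptom probabilities, non-infected patients low
#' ones. Images are rendered lazily by [cohort_image()] — the cohort object
#' itself holds only the manifest, questionnaires and per-image parameters.
#'
#' @param n_patients number of patients.
#' @param prevalence infection probability per patient in \[0, 1\].
#' @param images_per_patient visits per patient (default 2: days 3 and 10).
#' @param effect separation parameters: `intensity_neg` and `intensity_pos`
#'   (uniform ranges of erythema intensity for the two classes) and the
#'   per-item symptom probabilities `q_pos`, `q_neg` plus VAS ranges.
#' @param scene base [wound_scene_params()] shared by all images (its
#'   `erythema_intensity`, `incision$orientation_deg` and `seed` are
#'   overridden per image).
#' @param seed cohort seed.
#' @return A `wound_cohort`: `manifest` data frame (one row per image:
#'   `image_id`, `patient_code`, `visit_day`, `truth`,
#'   `erythema_intensity`, `image_seed`, questionnaire file key), list
#'   `questionnaires`, list `image_params`, and the generation record.
#' @export
generate_cohort <- function(n_patients, prevalence = 0.122,
                            images_per_patient = 2,
                            effect = cohort_effect(),
                            scene = wound_scene_params(),
                            seed = 1) {
  stopifnot(n_patients >= 1, prevalence >= 0, prevalence <= 1,
            images_per_patient >= 1)
  with_local_seed(seed, {
    infected <- rbinom(n_patients, 1, prevalence)
    days <- if (images_per_patient == 2) c(3L, 10L) else
      as.integer(seq_len(images_per_patient))
    rows <- list(); qs <- list(); iparams <- list(); idx <- 0L
    for (p in seq_len(n_patients)) {
      code <- sprintf("P%04d", p)
      for (v in seq_len(images_per_patient)) {
        idx <- idx + 1L
        rng <- if (infected[p] == 1) effect$intensity_pos else effect$intensity_neg
        intensity <- runif(1, rng[1], rng[2])
        orient <- runif(1, 0, 180)
        iseed <- sample.int(.Machine$integer.max - 1L, 1)
        pr <- scene
        pr$erythema_intensity <- intensity
        pr$incision$orientation_deg <- orient
        pr$seed <- iseed
        iparams[[idx]] <- pr
        probs <- if (infected[p] == 1) effect$q_pos else effect$q_neg
        vr <- if (infected[p] == 1) effect$vas_pos else effect$vas_neg
        qs[[idx]] <- validate_record(list(
          vas = sample(vr[1]:vr[2], 1),
          redness = rbinom(1, 1, probs["redness"]),
          burning = rbinom(1, 1, probs["burning"]),
          opening = rbinom(1, 1, probs["opening"]),
          swelling = rbinom(1, 1, probs["swelling"]),
          secretion = rbinom(1, 1, probs["secretion"]),
          fever = rbinom(1, 1, probs["fever"]),
          patient_code = code))
        rows[[idx]] <- data.frame(image_id = sprintf("img%04d", idx),
                                  patient_code = code,
                                  visit_day = days[v],
                                  truth = as.integer(intensity > scene$label_cutoff),
                                  erythema_intensity = intensity,
                                  image_seed = iseed,
                                  orientation_deg = orient)
      }
    }
    manifest <- do.call(rbind, rows)
    structure(list(manifest = manifest, questionnaires = qs,
                   image_params = iparams,
                   n_patients = n_patients, prevalence = prevalence,
                   effect = effect, scene = scene, seed = seed),
              class = "wound_cohort")
  })
}

#' Default cohort effect-separation parameters
#'
#' The generative conditions of the synthetic study: erythema intensity is
#' uniform on \[0.05, 0.45\] for non-infected and \[0.55, 0.95\] for
#' infected wounds (the generative infection cutoff on intensity is 0.5),
#' and per-item symptom probabilities reflect typical SSI presentation.
#'
#' @param intensity_neg,intensity_pos uniform erythema-intensity ranges.
#' @param q_neg,q_pos named per-item Bernoulli probabilities.
#' @param vas_neg,vas_pos inclusive VAS ranges.
#' @return A list of the generative parameters.
#' @export
cohort_effect <- function(intensity_neg = c(0.05, 0.45),
                          intensity_pos = c(0.55, 0.95),
                          q_neg = c(redness = 0.10, burning = 0.10,
                                    opening = 0.02, swelling = 0.10,
                                    secretion = 0.05, fever = 0.02),
                          q_pos = c(redness = 0.90, burning = 0.70,
                                    opening = 0.25, swelling = 0.70,
                                    secretion = 0.60, fever = 0.50),
                          vas_neg = c(0, 3), vas_pos = c(4, 9)) {
  list(intensity_neg = intensity_neg, intensity_pos = intensity_pos,
       q_neg = q_neg, q_pos = q_pos, vas_neg = vas_neg, vas_pos = vas_pos)
}

#' @export
print.wound_cohort <- function(x, ...) {
  cat(sprintf("<wound_cohort> %d patients, %d images, %d infected image(s), seed %d\n",
              x$n_patients, nrow(x$manifest), sum(x$manifest$truth), x$seed))
  invisible(x)
}

#' Render one cohort image
#'
#' @param cohort a `wound_cohort`.
#' @param i image index (row of the manifest).
#' @return As [generate_wound_image()]: list `image`, `truth`.
#' @export
cohort_image <- function(cohort, i) {
  stopifnot(inherits(cohort, "wound_cohort"),
            i >= 1, i <= nrow(cohort$manifest))
  generate_wound_image(cohort$image_params[[i]])
}

#' Write a cohort bundle to disk
#'
#' Layout: `images/*.png`, `masks/*.png` (staple masks, 0/255),
#' `questionnaires/*.json`, `manifest.csv`, `params.json` (exact
#' reproduction record).
#'
#' @param cohort a `wound_cohort`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  for (d in file.path(dir, c("", "images", "masks", "questionnaires")))
    dir.create(d, showWarnings = FALSE, recursive = TRUE)
  man <- cohort$manifest
  man$image_file <- file.path("images", paste0(man$image_id, ".png"))
  man$mask_file <- file.path("masks", paste0(man$image_id, ".png"))
  man$questionnaire_file <- file.path("questionnaires", paste0(man$image_id, ".json"))
  for (i in seq_len(nrow(man))) {
    sc <- cohort_image(cohort, i)
    write_wound_image(sc$image, file.path(dir, man$image_file[i]))
    write_wound_image(sc$truth$staple_mask, file.path(dir, man$mask_file[i]))
    q <- cohort$questionnaires[[i]]
    jsonlite::write_json(unclass(q)[!vapply(unclass(q), is.null, logical(1))],
                         file.path(dir, man$questionnaire_file[i]),
                         auto_unbox = TRUE, digits = NA)
  }
  write.csv(man, file.path(dir, "manifest.csv"), row.names = FALSE)
  rec <- list(n_patients = cohort$n_patients, prevalence = cohort$prevalence,
              seed = cohort$seed, effect = cohort$effect,
              scene = unclass(cohort$scene))
  jsonlite::write_json(rec, file.path(dir, "params.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}
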
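## Synthetic multi-view study generator.
##
## Emulates the structure the model assumes about paired-view radiology data:
## a study carries a latent set of lesions; each lesion maps to exactly one
## catalog tag and one templated report sentence, and stamps a geometric
## intensity pattern into the frontal and/or lateral image at a fixed
## per-lesion location (small jitter). One motif is visible only in the
## lateral view, so a model that fuses both views has information a
## frontal-only model cannot recover.

#' Default lesion motifs
#'
#' Eight motifs, each with a tag name, a templated finding sentence and a
#' per-view stamp (a disk or bar at a fixed relative location). The frontal
#' and lateral stamps of a motif differ; motif 8 ("hiatal hernia") has no
#' frontal stamp at all and is visible only laterally.
#'
#' @return list of motif definitions
#' @export
default_motifs <- function() {
  shape <- function(type, cy, cx, size, intensity) {
    list(type = type, cy = cy, cx = cx, size = size, intensity = intensity)
  }
  list(
    list(tag_name = "cardiomegaly",
         template = "the cardiac silhouette is enlarged consistent with cardiomegaly",
         frontal = shape("disk", 0.62, 0.45, 0.11, 0.55),
         lateral = shape("disk", 0.60, 0.35, 0.09, 0.50)),
    list(tag_name = "pleural effusion",
         template = "blunting of the costophrenic angle suggests a small pleural effusion",
         frontal = shape("hbar", 0.85, 0.25, 0.10, 0.60),
         lateral = shape("hbar", 0.88, 0.60, 0.12, 0.55)),
    list(tag_name = "pulmonary nodule",
         template = "a rounded pulmonary nodule is seen in the upper lobe",
         frontal = shape("disk", 0.22, 0.70, 0.05, 0.70),
         lateral = shape("disk", 0.25, 0.62, 0.04, 0.65)),
    list(tag_name = "atelectasis",
         template = "linear opacity at the base is consistent with atelectasis",
         frontal = shape("hbar", 0.75, 0.68, 0.11, 0.50),
         lateral = shape("vbar", 0.72, 0.80, 0.10, 0.50)),
    list(tag_name = "consolidation",
         template = "patchy airspace consolidation is present in the lower lobe",
         frontal = shape("disk", 0.55, 0.78, 0.08, 0.45),
         lateral = shape("disk", 0.50, 0.70, 0.07, 0.45)),
    list(tag_name = "emphysema",
         template = "the lungs are hyperexpanded consistent with emphysema",
         frontal = shape("vbar", 0.35, 0.15, 0.12, 0.45),
         lateral = shape("hbar", 0.30, 0.25, 0.12, 0.45)),
    list(tag_name = "rib fracture",
         template = "an acute displaced rib fracture is identified laterally",
         frontal = shape("vbar", 0.40, 0.90, 0.07, 0.65),
         lateral = shape("disk", 0.42, 0.12, 0.05, 0.60)),
    list(tag_name = "hiatal hernia",
         template = "a retrocardiac hiatal hernia is seen on the lateral view",
         frontal = NULL,
         lateral = shape("disk", 0.78, 0.45, 0.08, 0.70))
  )
}

#' Synthetic dataset configuration
#'
#' @param n_studies number of studies to generate
#' @param image_size side length in pixels (>= 32)
#' @param n_motifs how many of the default motifs to use (1..8)
#' @param max_lesions_per_study the lesion count per study is drawn uniformly
#'   from \{0, ..., max_lesions_per_study\}
#' @param noise_sd standard deviation of additive Gaussian pixel noise
#' @param normal_sentences report used verbatim for lesion-free studies
#' @param opening_sentence fixed first sentence of abnormal reports
#' @param seed integer seed; the whole dataset is a pure function of it
#' @return list of class `rg_synth_config`
#' @export
synth_config <- function(n_studies,
                         image_size = 64L,
                         n_motifs = 8L,
                         max_lesions_per_study = 3L,
                         noise_sd = 0.02,
                         normal_sentences = c(
                           "the lungs are clear bilaterally",
                           "the heart size is within normal limits",
                           "no acute cardiopulmonary abnormality"),
                         opening_sentence =
                           "the following abnormal findings are noted",
                         seed = 1L) {
  motifs <- default_motifs()
  if (image_size < 32L) stopf("image_size must be >= 32")
  if (n_motifs < 1L || n_motifs > length(motifs)) {
    stopf("n_motifs must be between 1 and %d", length(motifs))
  }
  cfg <- list(n_studies = as.integer(n_studies),
              image_size = as.integer(image_size),
              n_motifs = as.integer(n_motifs),
              max_lesions_per_study = as.integer(max_lesions_per_study),
              noise_sd = noise_sd,
              normal_sentences = normal_sentences,
              opening_sentence = opening_sentence,
              motifs = motifs[seq_len(n_motifs)],
              background = 0.1,
              seed = as.integer(seed))
  class(cfg) <- "rg_synth_config"
  cfg
}

stamp_shape <- function(img, sh, size, jitter_y = 0L, jitter_x = 0L) {
  cy <- sh$cy * size + jitter_y
  cx <- sh$cx * size + jitter_x
  r <- matrix(seq_len(size), size, size)
  c <- matrix(seq_len(size), size, size, byrow = TRUE)
  half <- sh$size * size
  mask <- switch(sh$type,
    disk = (r - cy)^2 + (c - cx)^2 <= half^2,
    hbar = abs(r - cy) <= pmax(1.5, half * 0.3) & abs(c - cx) <= half,
    vbar = abs(c - cx) <= pmax(1.5, half * 0.3) & abs(r - cy) <= half,
    stopf("unknown stamp type %s", sh$type))
  img[mask] <- img[mask] + sh$intensity
  img
}

#' Render the frontal/lateral image pair for a set of motifs
#'
#' Images are the constant background plus each motif's per-view stamp (with
#' a small placement jitter drawn from the current RNG stream) plus Gaussian
#' noise, clipped to `[0, 1]`. Motifs without a stamp for a view leave that
#' view untouched.
#'
#' @param motif_ids integer vector of motif indices (possibly empty)
#' @param config an `rg_synth_config`
#' @return list with `frontal` and `lateral` matrices in `[0, 1]`
#' @export
render_views <- function(motif_ids, config) {
  size <- config$image_size
  jmax <- max(1L, round(0.02 * size))
  fr <- matrix(config$background, size, size)
  la <- matrix(config$background, size, size)
  for (m in motif_ids) {
    mot <- config$motifs[[m]]
    jy <- sample.int(2L * jmax + 1L, 1L) - jmax - 1L
    jx <- sample.int(2L * jmax + 1L, 1L) - jmax - 1L
    if (!is.null(mot$frontal)) fr <- stamp_shape(fr, mot$frontal, size, jy, jx)
    jy <- sample.int(2L * jmax + 1L, 1L) - jmax - 1L
    jx <- sample.int(2L * jmax + 1L, 1L) - jmax - 1L
    if (!is.null(mot$lateral)) la <- stamp_shape(la, mot$lateral, size, jy, jx)
  }
  if (config$noise_sd > 0) {
    fr <- fr + matrix(stats::rnorm(size^2, 0, config$noise_sd), size, size)
    la <- la + matrix(stats::rnorm(size^2, 0, config$noise_sd), size, size)
  }
  list(frontal = pmin(pmax(fr, 0), 1), lateral = pmin(pmax(la, 0), 1))
}

#' Compose the templated report for a motif set
#'
#' Lesion-free studies receive the fixed normal-findings report; otherwise
#' the report is the fixed opening sentence followed by one templated
#' sentence per motif, in catalog order (so the report is a pure function of
#' the motif set).
#'
#' @param motif_ids integer vector of motif indices
#' @param config an `rg_synth_config`
#' @return character vector of sentences
#' @export
compose_report <- function(motif_ids, config) {
  if (length(motif_ids) == 0L) return(config$normal_sentences)
  ids <- sort(unique(as.integer(motif_ids)))
  c(config$opening_sentence,
    vapply(ids, function(m) config$motifs[[m]]$template, character(1)))
}

#' Generate a synthetic dataset on disk
#'
#' Writes `images/` (8-bit grayscale PNGs), `manifest.jsonl` and `tags.csv`
#' under `out_dir`. Per study the lesion count `k` is drawn uniformly from
#' \{0..max\}, then `k` distinct motifs are drawn uniformly. Fully
#' reproducible: the same config (incl. seed) yields byte-identical files.
#'
#' @param config an `rg_synth_config`
#' @param out_dir output directory (created if needed)
#' @return list with `studies` (list of [study()]) and `catalog`
#' @export
make_dataset <- function(config, out_dir) {
  stopifnot(inherits(config, "rg_synth_config"))
  dir.create(file.path(out_dir, "images"), recursive = TRUE,
             showWarnings = FALSE)
  catalog <- tag_catalog(vapply(config$motifs, `[[`, character(1), "tag_name"))
  studies <- with_local_seed(config$seed, {
    lapply(seq_len(config$n_studies), function(i) {
      k <- sample.int(config$max_lesions_per_study + 1L, 1L) - 1L
      ids <- if (k > 0L) sort(sample.int(config$n_motifs, k)) else integer(0)
      views <- render_views(ids, config)
      sid <- sprintf("study_%04d", i)
      fp <- file.path("images", paste0(sid, "_frontal.png"))
      lp <- file.path("images", paste0(sid, "_lateral.png"))
      png::writePNG(views$frontal, file.path(out_dir, fp))
      png::writePNG(views$lateral, file.path(out_dir, lp))
      study(sid, fp, lp,
            tags = catalog$names[ids],
            report = compose_report(ids, config))
    })
  })
  write_manifest(studies, file.path(out_dir, "manifest.jsonl"))
  write_tag_catalog(catalog, file.path(out_dir, "tags.csv"))
  # re-read so image paths resolve absolutely against out_dir
  list(studies = read_manifest(file.path(out_dir, "manifest.jsonl")),
       catalog = catalog)
}
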
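# Seeded synthetic stand-ins for single-ingredient photos and multi-
# ingredient scenes. Classes are procedural textures: separable by colour
# distribution, with hues shared pairwise so classes are not trivially
# distinct, mimicking inter-class colour similarity of real ingredients.

hsv_to_rgb <- function(h, s, v) {
  h <- (h %% 1) * 6
  i <- floor(h)
  f <- h - i
  p <- v * (1 - s); q <- v * (1 - s * f); t <- v * (1 - s * (1 - f))
  switch(as.character(i %% 6),
         "0" = c(v, t, p), "1" = c(q, v, p), "2" = c(p, v, t),
         "3" = c(p, q, v), "4" = c(t, p, v), "5" = c(v, p, q))
}

#' Specification of one synthetic ingredient class
#'
#' A class is a texture family plus a base hue; its variants perturb hue,
#' pattern scale and orientation, standing in for the distinct visual
#' appearances one ingredient takes under different cutting/cooking
#' conditions.
#'
#' @param id 0-based class id (doubles as the level-4 label).
#' @param texture one of `"stripes"`, `"spots"`, `"checker"`, `"gradient"`,
#'   `"speckle"`.
#' @param base_hue hue in `[0, 1)`.
#' @param fg_fraction fraction of pixels taking the secondary colour.
#' @param fg_value brightness of the secondary colour.
#' @param scale base pattern period in pixels.
#' @param variants list of perturbations, each
#'   `list(hue_shift =, scale_mult =, orientation =)`.
#' @return A `synthetic_class_spec`.
#' @export
synthetic_class_spec <- function(id, texture, base_hue, fg_fraction = 0.5,
                                 fg_value = 0.45, scale = 8,
                                 variants = list(list(hue_shift = 0,
                                                      scale_mult = 1,
                                                      orientation = 0))) {
  texture <- match.arg(texture,
    c("stripes", "spots", "checker", "gradient", "speckle"))
  stopifnot(length(variants) >= 1L, fg_fraction > 0, fg_fraction < 1)
  structure(list(id = as.integer(id), texture = texture,
                 base_hue = base_hue, fg_fraction = fg_fraction,
                 fg_value = fg_value, scale = scale, variants = variants),
            class = "synthetic_class_spec")
}

#' Default bank of synthetic ingredient classes
#'
#' Classes `2m-1` and `2m` share a base hue but differ in texture family,
#' foreground fraction and secondary-colour brightness, so every class has a
#' distinct pixel-colour distribution (required for the 1x1-kernel variant,
#' whose pre-pooling receptive field is a single pixel) while hue alone does
#' not separate all pairs. Hues span the red-to-green range typical of food
#' and deliberately avoid blue: the evaluation convention paints backgrounds
#' pure blue precisely because that colour is rare in ingredients.
#'
#' @param n_classes number of classes (default 8).
#' @param n_variants visual variants per class (default 2).
#' @return List of [synthetic_class_spec()].
#' @export
default_class_specs <- function(n_classes = 8L, n_variants = 2L) {
  fams <- c("stripes", "spots", "checker", "gradient", "speckle")
  lapply(seq_len(n_classes) - 1L, function(i) {
    pair <- i %/% 2L
    alt <- i %% 2L
    variants <- lapply(seq_len(n_variants), function(v)
      list(hue_shift = 0.03 * (v - 1L),
           scale_mult = 1 + 0.5 * (v - 1L),
           orientation = (v - 1L) * pi / 4))
    synthetic_class_spec(
      id = i,
      texture = fams[(i %% length(fams)) + 1L],
      base_hue = 0.45 * pair / max(1L, ceiling(n_classes / 2L) - 1L),
      fg_fraction = if (alt == 0L) 0.5 else 0.2,
      fg_value = if (alt == 0L) 0.35 else 0.75,
      scale = 6 + 2 * alt,
      variants = variants)
  })
}

# smooth low-frequency noise field in [0,1], used by the "spots" family
smooth_noise <- function(h, w, cells = 8L) {
  g <- matrix(stats::runif((cells + 1L)^2), cells + 1L, cells + 1L)
  resize_bilinear(array(g, dim = c(cells + 1L, cells + 1L, 1L)), h, w)[, , 1L]
}

#' Render one synthetic single-ingredient image
#'
#' Produces a full-frame texture for the class/variant. Deterministic given
#' `seed`: the same call always renders the identical image.
#'
#' @param spec a [synthetic_class_spec()].
#' @param variant 1-based variant index.
#' @param seed integer seed.
#' @param size square image side (default 64).
#' @param noise_sd additive Gaussian pixel noise (default 0.02).
#' @return `list(image, label)`: an `size x size x 3` array in `[0, 1]` and
#'   the 0-based class id.
#' @export
generate_single_ingredient_image <- function(spec, variant = 1L, seed = 1L,
                                             size = 64L, noise_sd = 0.02) {
  stopifnot(inherits(spec, "synthetic_class_spec"))
  if (variant < 1L || variant > length(spec$variants))
    stop("class ", spec$id, " has no variant ", variant)
  v <- spec$variants[[variant]]
  with_seed(seed, {
    hue <- spec$base_hue + v$hue_shift
    base_col <- hsv_to_rgb(hue, 0.85, 0.85)
    fg_col <- hsv_to_rgb(hue + 0.04, 0.55, spec$fg_value)
    sc <- spec$scale * v$scale_mult
    th <- v$orientation
    xy <- expand.grid(y = seq_len(size), x = seq_len(size))
    u <- (xy$x * cos(th) + xy$y * sin(th)) / sc
    field <- switch(spec$texture,
      stripes = matrix(sin(2 * pi * u), size, size),
      checker = matrix(sin(2 * pi * xy$x / sc) * sin(2 * pi * xy$y / sc),
                       size, size),
      gradient = matrix(u / max(abs(u)), size, size),
      spots = smooth_noise(size, size, max(2L, round(size / sc))),
      speckle = matrix(stats::runif(size^2), size, size))
    thr <- stats::quantile(field, 1 - spec$fg_fraction)
    if (spec$texture == "gradient") {
      w <- (field - min(field)) / (max(field) - min(field))
      img <- array(0, dim = c(size, size, 3L))
      for (c in 1:3)
        img[, , c] <- base_col[c] * (1 - w) + fg_col[c] * w
    } else {
      pat <- field > thr
      img <- array(rep(base_col, each = size^2), dim = c(size, size, 3L))
      for (c in 1:3) img[, , c][pat] <- fg_col[c]
    }
    img <- img + array(stats::rnorm(size^2 * 3L, sd = noise_sd),
                       dim = dim(img))
    list(image = pmin(pmax(img, 0), 1), label = spec$id)
  })
}

#' Generate a labelled single-ingredient dataset with an 80/20 split
#'
#' Renders `images_per_variant` images for every class/variant and splits
#' them 80/20 into train/test, stratified by class with seed-stable
#' membership. With a taxonomy, hierarchical labels are attached by lifting
#' each leaf id.
#'
#' @param class_specs list of [synthetic_class_spec()].
#' @param tax optional [ingredient_taxonomy()]; class ids must then be valid
#'   level-4 ids.
#' @param images_per_variant images per visual variant (default 6; the
#'   emulated collection protocol selects 5--10).
#' @param size image side (default 64).
#' @param seed master seed; drives rendering and the split.
#' @param train_frac training fraction (default 0.8).
#' @return `list(images, labels, hierarchical, manifest)`: `manifest` is a
#'   data.frame with `class_id`, `variant`, `item`, `split`.
#' @export
generate_dataset <- function(class_specs, tax = NULL, images_per_variant = 6L,
                             size = 64L, seed = 1L, train_frac = 0.8) {
  stopifnot(images_per_variant >= 2L)
  plan <- do.call(rbind, lapply(class_specs, function(sp)
    expand.grid(class_id = sp$id, variant = seq_along(sp$variants),
                item = seq_len(images_per_variant))))
  seeds <- with_seed(seed, sample.int(.Machine$integer.max - 1L, nrow(plan)))
  by_id <- stats::setNames(class_specs,
                           vapply(class_specs, `[[`, integer(1), "id"))
  images <- vector("list", nrow(plan))
  for (r in seq_len(nrow(plan))) {
    sp <- by_id[[as.character(plan$class_id[r])]]
    images[[r]] <- generate_single_ingredient_image(
      sp, plan$variant[r], seeds[r], size)$image
  }
  labels <- as.integer(plan$class_id)
  is_train <- train_test_split(labels, train_frac, seed = seed)
  plan$split <- ifelse(is_train, "train", "test")
  hier <- NULL
  if (!is.null(tax))
    hier <- do.call(rbind, lapply(labels, function(l)
      as.integer(lift_label(tax, l))))
  list(images = images, labels = labels, hierarchical = hier,
       manifest = plan)
}

#' Specification of a synthetic multi-ingredient scene
#'
#' @param k number of ingredient regions.
#' @param size image side (default 64).
#' @param layout region geometry; `"voronoi"` partitions a central dish disc
#'   among `k` random sites.
#' @param min_region_frac smallest admissible region, as a fraction of all
#'   pixels (default 0.01); layouts violating it are resampled.
#' @param noise_sd additive pixel noise in the rendered scene.
#' @param seed integer seed.
#' @return A `scene_spec`.
#' @export
scene_spec <- function(k, size = 64L, layout = "voronoi",
                       min_region_frac = 0.01, noise_sd = 0.02, seed = 1L) {
  stopifnot(k >= 1L, size >= 16L, layout == "voronoi",
            min_region_frac > 0, min_region_frac <= 1 / k)
  structure(list(k = as.integer(k), size = as.integer(size), layout = layout,
                 min_region_frac = min_region_frac, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "scene_spec")
}

#' Compose a multi-ingredient scene with exact ground truth
#'
#' Renders `k` ingredient textures into the cells of a Voronoi partition of
#' a central dish disc; pixels outside the disc are background (label 0).
#' The label map and the rendered image are pixel-aligned by construction --
#' no anti-aliased boundary pixels exist. A variant with the background
#' painted pure blue (the evaluation convention) is returned alongside a
#' plain grey-background version.
#'
#' @param spec a [scene_spec()].
#' @param class_specs list of at least `k` [synthetic_class_spec()]; the
#'   first `k` supply the region textures (region `i` uses class
#'   `class_specs[[i]]`).
#' @return `list(image, image_plain, label_map, masks, class_ids)`: `image`
#'   has the blue background, `label_map` holds `0` (background) and `1..k`,
#'   `masks` is the list of per-region logical masks.
#' @export
compose_multi_ingredient_scene <- function(spec, class_specs) {
  stopifnot(inherits(spec, "scene_spec"), length(class_specs) >= spec$k)
  sz <- spec$size; k <- spec$k
  with_seed(spec$seed, {
    ctr <- (sz + 1) / 2
    radius <- 0.45 * sz
    xy <- expand.grid(y = seq_len(sz), x = seq_len(sz))
    in_disc <- matrix((xy$y - ctr)^2 + (xy$x - ctr)^2 <= radius^2, sz, sz)
    label_map <- NULL
    for (attempt in 1:50) {
      sites <- cbind(stats::runif(k, ctr - 0.6 * radius, ctr + 0.6 * radius),
                     stats::runif(k, ctr - 0.6 * radius, ctr + 0.6 * radius))
      d2 <- sapply(seq_len(k), function(i)
        (xy$y - sites[i, 1L])^2 + (xy$x - sites[i, 2L])^2)
      lab <- matrix(max.col(-matrix(d2, ncol = k), ties.method = "first"),
                    sz, sz)
      lab[!in_disc] <- 0L
      counts <- tabulate(lab[lab > 0L], k)
      if (all(counts >= spec$min_region_frac * sz^2)) {
        label_map <- lab
        break
      }
      message("scene layout attempt ", attempt,
              " produced a too-small region; resampling sites")
    }
    if (is.null(label_map))
      stop("could not place ", k, " regions of at least ",
           spec$min_region_frac * 100, "% pixels each")
    tex_seeds <- sample.int(.Machine$integer.max - 1L, k)
    img <- array(0.82, dim = c(sz, sz, 3L))       # neutral grey background
    for (i in seq_len(k)) {
      tex <- generate_single_ingredient_image(
        class_specs[[i]], 1L, tex_seeds[i], sz, noise_sd = 0)$image
      sel <- label_map == i
      for (c in 1:3) img[, , c][sel] <- tex[, , c][sel]
    }
    img <- pmin(pmax(img + array(stats::rnorm(sz^2 * 3L, sd = spec$noise_sd),
                                 dim = dim(img)), 0), 1)
    blue <- blue_background_composite(img, label_map)
    masks <- lapply(seq_len(k), function(i) label_map == i)
    list(image = blue, image_plain = img, label_map = label_map,
         masks = masks,
         class_ids = vapply(class_specs[seq_len(k)], `[[`, integer(1), "id"))
  })
}
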
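# BCGAN: per-class generative-adversarial augmentation for cell images.
#
# The generator maps a noise vector z to an image via a dense projection
# followed by upsampling convolution blocks (batch norm, LeakyReLU,
# dropout) and a final tanh; the discriminator stacks convolution blocks
# with LeakyReLU, max pooling, batch norm, and dropout into a sigmoid
# real/fake score. Training alternates S discriminator ascent steps on
#     (1/n) sum[ log D(x_i) + log(1 - D(G(z_i))) ]
# with one generator descent step on (1/n) sum log(1 - D(G(z_i))) per
# iteration, the empirical two-player value of the minimax game
#     min_G max_D  E_x[log D(x)] + E_z[log(1 - D(G(z)))].
# Distinguishing choices for this variant: five generator blocks, kernel
# size 5 (mitigating checkerboard artifacts of small-kernel upsampling),
# and dropout + batch norm in both players. One GAN is trained per class.

#' BCGAN configuration
#'
#' @param noise_dim Length of the latent noise vector z (default 100).
#' @param image_size Generated image size `c(H, W)`; both sides must be
#'   divisible by `2^gen_blocks` (each generator block doubles resolution).
#' @param gen_blocks Number of upsampling convolution blocks (default 5).
#' @param kernel_size Convolution kernel size, >= 4 (larger kernels temper
#'   checkerboard artifacts; default 5).
#' @param base_filters Filter count of the last generator block; widths
#'   double per block toward the coarse end (default 32).
#' @param disc_blocks Discriminator convolution blocks (default 3).
#' @param dropout_rate Dropout rate in both players, in \[0, 1).
#' @param leaky_slope Negative slope of LeakyReLU (default 0.2).
#' @param mini_batch Samples per update (default 10).
#' @param learning_rate Adam step size (default 1e-4).
#' @param iterations Training iterations T.
#' @param disc_steps Discriminator steps S per iteration (default 1).
#' @param seed Integer seed governing init, noise, dropout, and batches.
#' @return A `gan_config` list.
#' @export
gan_config <- function(noise_dim = 100, image_size = c(64, 64),
                       gen_blocks = 5, kernel_size = 5, base_filters = 32,
                       disc_blocks = 3, dropout_rate = 0.3,
                       leaky_slope = 0.2, mini_batch = 10,
                       learning_rate = 1e-4, iterations = 200,
                       disc_steps = 1, seed = 1) {
  cfg <- list(noise_dim = assert_scalar_int(noise_dim, "noise_dim"),
              image_size = as.integer(image_size),
              gen_blocks = assert_scalar_int(gen_blocks, "gen_blocks"),
              kernel_size = assert_scalar_int(kernel_size, "kernel_size"),
              base_filters = assert_scalar_int(base_filters, "base_filters"),
              disc_blocks = assert_scalar_int(disc_blocks, "disc_blocks"),
              dropout_rate = dropout_rate,
              leaky_slope = leaky_slope,
              mini_batch = assert_scalar_int(mini_batch, "mini_batch"),
              learning_rate = learning_rate,
              iterations = assert_scalar_int(iterations, "iterations"),
              disc_steps = assert_scalar_int(disc_steps, "disc_steps"),
              seed = as.integer(seed))
  if (cfg$kernel_size < 4L) {
    abort("`kernel_size` must be >= 4 (checkerboard mitigation)")
  }
  if (dropout_rate < 0 || dropout_rate >= 1) {
    abort("`dropout_rate` must lie in [0, 1)")
  }
  stopifnot(learning_rate > 0, leaky_slope > 0)
  validate_gan_geometry(cfg)
  structure(cfg, class = "gan_config")
}

#' Conventional-GAN preset
#'
#' The plain baseline configuration: dropout off, kernel 3, four generator
#' blocks — the variant without this package's stabilizing choices. Useful
#' for ablation-style comparisons against [gan_config()].
#'
#' @inheritParams gan_config
#' @param ... Further overrides passed to the config list.
#' @return A `gan_config` list.
#' @export
gan_config_plain <- function(image_size = c(64, 64), base_filters = 32,
                             ...) {
  cfg <- gan_config(image_size = image_size, base_filters = base_filters,
                    gen_blocks = 4, kernel_size = 4, dropout_rate = 0, ...)
  cfg$kernel_size <- 3L            # preset deliberately below the BCGAN bound
  cfg
}

validate_gan_geometry <- function(cfg) {
  div <- 2L^cfg$gen_blocks
  if (any(cfg$image_size %% div != 0L) || any(cfg$image_size %/% div < 1L)) {
    near <- pmax(div, div * round(cfg$image_size / div))
    abort(sprintf(
      "image_size %s not reachable by %d doubling blocks; nearest valid size is %s",
      paste(cfg$image_size, collapse = "x"), cfg$gen_blocks,
      paste(near, collapse = "x")))
  }
  ddiv <- 2L^cfg$disc_blocks
  if (any(cfg$image_size %% ddiv != 0L)) {
    abort(sprintf("image_size must be divisible by 2^disc_blocks = %d", ddiv))
  }
  invisible(cfg)
}

#' Build the BCGAN generator network
#'
#' Dense projection of the noise vector to a coarse feature map, then
#' `gen_blocks` blocks of (nearest upsample x2, convolution, batch norm,
#' LeakyReLU, dropout), then a convolution to 3 channels with tanh, so
#' outputs lie in \[-1, 1\]. Filter widths double per block toward the
#' coarse end, starting from `base_filters` at the output side.
#'
#' @param cfg A [gan_config()].
#' @return A network list (see [gan_generate()]).
#' @export
build_generator <- function(cfg) {
  validate_gan_geometry(cfg)
  h0 <- cfg$image_size[1] %/% 2L^cfg$gen_blocks
  w0 <- cfg$image_size[2] %/% 2L^cfg$gen_blocks
  widths <- cfg$base_filters * 2L^((cfg$gen_blocks - 1L):0L)
  layers <- list(nn_dense(cfg$noise_dim, h0 * w0 * widths[1]),
                 nn_reshape(h0, w0, widths[1]))
  c_prev <- widths[1]
  for (i in seq_len(cfg$gen_blocks)) {
    layers <- c(layers, list(
      nn_upsample(),
      nn_conv(c_prev, widths[i], cfg$kernel_size),
      nn_bn(widths[i], "conv"),
      nn_act("lrelu", cfg$leaky_slope)))
    if (cfg$dropout_rate > 0) {
      layers <- c(layers, list(nn_dropout(cfg$dropout_rate)))
    }
    c_prev <- widths[i]
  }
  layers <- c(layers, list(nn_conv(c_prev, 3L, cfg$kernel_size),
                           nn_act("tanh")))
  list(layers = layers)
}

#' Build the BCGAN discriminator network
#'
#' Stacked blocks of (convolution, LeakyReLU, 2x2 max pool, batch norm,
#' dropout) followed by a dense sigmoid score in (0, 1).
#'
#' @param cfg A [gan_config()].
#' @return A network list.
#' @export
build_discriminator <- function(cfg) {
  validate_gan_geometry(cfg)
  layers <- list()
  c_prev <- 3L
  for (i in seq_len(cfg$disc_blocks)) {
    w <- cfg$base_filters * 2L^(i - 1L)
    layers <- c(layers, list(
      nn_conv(c_prev, w, cfg$kernel_size),
      nn_act("lrelu", cfg$leaky_slope),
      nn_maxpool(),
      nn_bn(w, "conv")))
    if (cfg$dropout_rate > 0) {
      layers <- c(layers, list(nn_dropout(cfg$dropout_rate)))
    }
    c_prev <- w
  }
  hw <- prod(cfg$image_size %/% 2L^cfg$disc_blocks)
  layers <- c(layers, list(nn_flatten(),
                           nn_dense(hw * c_prev, 1L),
                           nn_act("sigmoid")))
  list(layers = layers)
}

#' Empirical GAN value function
#'
#' `mean(log(d_real)) + mean(log(1 - d_fake))` — the empirical two-player
#' value F(D, G) the discriminator ascends and the generator (through its
#' second term) descends. Scores exactly at 0 or 1 are clamped to
#' `[1e-7, 1 - 1e-7]` with a warning.
#'
#' @param d_real Discriminator scores on real samples, in (0, 1).
#' @param d_fake Discriminator scores on generated samples, in (0, 1).
#' @return A single number (non-positive at the uninformative point
#'   `d == 0.5`, where it equals `2 log 0.5`).
#' @examples
#' gan_value(0.5, 0.5)   # 2 * log(0.5)
#' @export
gan_value <- function(d_real, d_fake) {
  eps <- 1e-7
  if (any(d_real <= 0 | d_real >= 1) || any(d_fake <= 0 | d_fake >= 1)) {
    warn("discriminator scores at {0, 1} clamped to [1e-7, 1 - 1e-7]")
  }
  d_real <- pmin(pmax(d_real, eps), 1 - eps)
  d_fake <- pmin(pmax(d_fake, eps), 1 - eps)
  mean(log(d_real)) + mean(log(1 - d_fake))
}

# Generator forward pass on an n x noise_dim matrix of latents.
#' Generate images from latent noise
#'
#' @param pair A trained `gan_pair` (or a list with `$generator`).
#' @param z n x noise_dim latent matrix.
#' @param training Use batch statistics (TRUE) or running statistics.
#' @return An `[H, W, 3, n]` array in \[-1, 1\].
#' @export
gan_generate <- function(pair, z, training = FALSE) {
  nn_forward(pair$generator, z, training = training)$out
}

#' Train a BCGAN on one class of images
#'
#' Alternating optimization per Adam: each iteration runs `disc_steps`
#' discriminator updates (ascent on the empirical value, via two
#' mini-batches of real and generated samples) followed by one generator
#' update descending `mean(log(1 - D(G(z))))`. The full run is
#' deterministic given `cfg$seed`.
#'
#' @param images An [image_set], customarily a single class.
#' @param cfg A [gan_config()].
#' @return A `gan_pair`: `generator`, `discriminator`, `cfg`, and a
#'   `loss_history` tibble (`iteration`, `d_loss`, `g_loss`), where
#'   `d_loss` is the negated value function and `g_loss` the generator
#'   objective. Aborts with the iteration index if a loss turns
#'   non-finite.
#' @export
train_bcgan <- function(images, cfg = gan_config()) {
  stopifnot(inherits(images, "image_set"))
  if (length(images) < cfg$mini_batch) {
    abort("need at least `mini_batch` images")
  }
  x_all <- images_to_batch(images) * 2 - 1        # [-1, 1]
  if (!all(dim(x_all)[1:2] == cfg$image_size)) {
    abort("images must match cfg$image_size; resize at load time")
  }
  n_real <- dim(x_all)[4]
  nb <- cfg$mini_batch
  eps <- 1e-7
  with_seed(cfg$seed, {
    G <- build_generator(cfg)
    D <- build_discriminator(cfg)
    stG <- adam_init(G)
    stD <- adam_init(D)
    hist <- vector("list", cfg$iterations)
    for (t in seq_len(cfg$iterations)) {
      d_loss <- NA_real_
      for (s in seq_len(cfg$disc_steps)) {
        z <- matrix(rnorm(nb * cfg$noise_dim), nb, cfg$noise_dim)
        idx <- sample.int(n_real, nb, replace = n_real < nb)
        xr <- x_all[, , , idx, drop = FALSE]
        gf <- nn_forward(G, z, training = TRUE)
        G <- gf$net
        fr <- nn_forward(D, xr, training = TRUE)
        D <- fr$net
        p_real <- pmin(pmax(as.vector(fr$out), eps), 1 - eps)
        ff <- nn_forward(D, gf$out, training = TRUE)
        D <- ff$net
        p_fake <- pmin(pmax(as.vector(ff$out), eps), 1 - eps)
        # ascend mean log D(x) + mean log(1 - D(G(z)))  ==  descend negation
        dreal <- matrix(-1 / (nb * p_real), nb, 1)
        dfake <- matrix(1 / (nb * (1 - p_fake)), nb, 1)
        gr <- nn_backward(D, fr$caches, dreal)$grads
        gfk <- nn_backward(D, ff$caches, dfake)$grads
        gsum <- purrr::map2(gr, gfk,
                            function(a, b) purrr::map2(a, b, `+`))
        upd <- adam_step(D, gsum, stD, cfg$learning_rate)
        D <- upd$net
        stD <- upd$st
        d_loss <- -(mean(log(p_real)) + mean(log(1 - p_fake)))
      }
      # generator step on (1/n) sum log(1 - D(G(z)))
      z <- matrix(rnorm(nb * cfg$noise_dim), nb, cfg$noise_dim)
      gf <- nn_forward(G, z, training = TRUE)
      G <- gf$net
      ff <- nn_forward(D, gf$out, training = TRUE)   # state changes discarded
      p_fake <- pmin(pmax(as.vector(ff$out), eps), 1 - eps)
      g_loss <- mean(log(1 - p_fake))
      dfake <- matrix(-1 / (nb * (1 - p_fake)), nb, 1)
      dimg <- nn_backward(D, ff$caches, dfake)$dx
      gG <- nn_backward(G, gf$caches, dimg)$grads
      upd <- adam_step(G, gG, stG, cfg$learning_rate)
      G <- upd$net
      stG <- upd$st
      if (!is.finite(d_loss) || !is.finite(g_loss)) {
        abort(sprintf("non-finite GAN loss at iteration %d (d=%g, g=%g)",
                      t, d_loss, g_loss))
      }
      hist[[t]] <- tibble(iteration = t, d_loss = d_loss, g_loss = g_loss)
    }
    structure(list(generator = G, discriminator = D, cfg = cfg,
                   loss_history = dplyr::bind_rows(hist)),
              class = "gan_pair")
  })
}

#' Sample synthetic images from a trained BCGAN
#'
#' Draws `n` latents, generates images, rescales from \[-1, 1\] to
#' \[0, 255\], and (optionally) bilinearly resizes to the classifier input
#' size. Outputs carry `provenance = "synthetic"`.
#'
#' @param pair A trained `gan_pair`.
#' @param n Number of images (> 0).
#' @param class_label Integer class index assigned to every image.
#' @param seed Seed for the latent draws.
#' @param class_names Class table for the resulting [image_set].
#' @param image_size Optional output `c(H, W)` differing from the GAN
#'   resolution.
#' @return An [image_set] of `n` synthetic images.
#' @export
sample_images <- function(pair, n, class_label = 1, seed = 1,
                          class_names = NULL, image_size = NULL) {
  stopifnot(inherits(pair, "gan_pair"))
  n <- assert_scalar_int(n, "n")
  class_label <- assert_scalar_int(class_label, "class_label")
  class_names <- class_names %||%
    paste0("class", seq_len(max(class_label, 2L)))
  imgs <- with_seed(seed, {
    out <- vector("list", n)
    chunk <- 64L
    done <- 0L
    while (done < n) {
      nb <- min(chunk, n - done)
      z <- matrix(rnorm(nb * pair$cfg$noise_dim), nb, pair$cfg$noise_dim)
      xs <- gan_generate(pair, z, training = FALSE)
      for (i in seq_len(nb)) {
        im <- (xs[, , , i] + 1) / 2 * 255
        im <- pmin(pmax(im, 0), 255)
        if (!is.null(image_size) &&
            !all(dim(im)[1:2] == image_size)) {
          eb <- EBImage::resize(
            EBImage::Image(aperm(im / 255, c(2, 1, 3)),
                           colormode = "Color"),
            w = image_size[2], h = image_size[1])
          im <- pmin(pmax(aperm(as.array(eb), c(2, 1, 3)) * 255, 0), 255)
        }
        out[[done + i]] <- round(im)
      }
      done <- done + nb
    }
    out
  })
  image_set(imgs, rep(class_label, n), class_names,
            provenance = "synthetic")
}

#' @export
print.gan_pair <- function(x, ...) {
  cat(sprintf(
    "<gan_pair> %s image, %d generator blocks, kernel %d, %d iterations\n",
    paste(x$cfg$image_size, collapse = "x"), x$cfg$gen_blocks,
    x$cfg$kernel_size, nrow(x$loss_history)))
  invisible(x)
}
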
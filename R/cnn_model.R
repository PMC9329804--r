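#' Layer table of the compact motor-imagery CNN
#'
#' Reference specification of the three-convolution architecture: for each
#' layer its type, number of feature maps, output size, kernel, stride,
#' padding, and trainable parameter count. The input is one 32 x 512 sample
#' (32 channels, 512 time points); shapes chain as
#' 32x512 -> 32x256 -> 16x256 -> 8x64 -> 4x64 -> 2x16 -> 1024 -> 2.
#' Batch-normalization layers carry no trainable parameters (normalization
#' only), and the softmax is the standard parameter-free map, so the total
#' trainable count is 400 + 11,296 + 10,272 + 2,050 = 24,018.
#'
#' @param dropout spatial-dropout rate.
#' @return A [tibble::tibble], one row per layer.
#' @export
mi_cnn_spec <- function(dropout = 0.25) {
  tibble::tribble(
    ~layer,        ~type,      ~maps, ~out_h, ~out_w, ~k_h, ~k_w, ~s_h, ~s_w, ~p_h, ~p_w, ~params,
    "input",       "input",        1,     32,    512,   NA,   NA,   NA,   NA,   NA,   NA,       0,
    "conv1",       "conv",        16,     32,    256,    1,   24,    1,    2,    0,   11,     400,
    "bn1",         "batchnorm",   16,     32,    256,   NA,   NA,   NA,   NA,   NA,   NA,       0,
    "elu1",        "activation",  16,     32,    256,   NA,   NA,   NA,   NA,   NA,   NA,       0,
    "conv2",       "conv",        32,     16,    256,    2,   11,    2,    1,    0,    5,   11296,
    "bn2",         "batchnorm",   32,     16,    256,   NA,   NA,   NA,   NA,   NA,   NA,       0,
    "elu2",        "activation",  32,     16,    256,   NA,   NA,   NA,   NA,   NA,   NA,       0,
    "pool1",       "avgpool",     32,      8,     64,    2,    4,    2,    4,   NA,   NA,       0,
    "drop1",       "dropout",     32,      8,     64,   NA,   NA,   NA,   NA,   NA,   NA,       0,
    "conv3",       "conv",        32,      4,     64,    2,    5,    2,    1,    0,    2,   10272,
    "bn3",         "batchnorm",   32,      4,     64,   NA,   NA,   NA,   NA,   NA,   NA,       0,
    "elu3",        "activation",  32,      4,     64,   NA,   NA,   NA,   NA,   NA,   NA,       0,
    "pool2",       "avgpool",     32,      2,     16,    2,    4,    2,    4,   NA,   NA,       0,
    "drop2",       "dropout",     32,      2,     16,   NA,   NA,   NA,   NA,   NA,   NA,       0,
    "flatten",     "flatten",     NA,     NA,   1024,   NA,   NA,   NA,   NA,   NA,   NA,       0,
    "fc",          "dense",       NA,     NA,      2,   NA,   NA,   NA,   NA,   NA,   NA,    2050,
    "softmax",     "softmax",     NA,     NA,      2,   NA,   NA,   NA,   NA,   NA,   NA,       0
  ) |>
    dplyr::mutate(dropout_rate = ifelse(.data$type == "dropout", dropout, NA))
}

#' Build the compact CNN
#'
#' Constructs every layer from the specification table, verifying at each
#' step that the computed output shape and trainable parameter count equal
#' the declared row; construction fails at the first inconsistent layer.
#' Weights use He-normal initialization, deterministic given `seed`.
#'
#' @param spec layer table from [mi_cnn_spec()].
#' @param in_shape input sample shape `c(channels, time)`.
#' @param seed RNG seed for weight initialization.
#' @param classes class labels in output order.
#' @return An `mi_cnn` model object.
#' @export
build_mi_cnn <- function(spec = mi_cnn_spec(), in_shape = c(32, 512),
                         seed = 1, classes = c("left", "right")) {
  set.seed(seed)
  cur <- c(1L, in_shape[1], in_shape[2])   # (maps, h, w)
  layers <- list()
  check <- function(row, got_shape, got_params) {
    want <- c(row$maps, row$out_h, row$out_w)
    if (row$type %in% c("flatten", "dense", "softmax"))
      want <- c(NA, NA, row$out_w)
    ok_shape <- all(is.na(want) | want == got_shape)
    if (!ok_shape)
      stop("layer '", row$layer, "': computed shape ",
           paste(got_shape, collapse = "x"), " does not match declared ",
           paste(want, collapse = "x"))
    if (!is.na(row$params) && row$params != got_params)
      stop("layer '", row$layer, "': computed parameter count ", got_params,
           " does not match declared ", row$params)
  }
  for (i in seq_len(nrow(spec))) {
    row <- spec[i, ]
    lyr <- switch(
      row$type,
      input = {
        check(row, cur, 0)
        list(type = "input")
      },
      conv = {
        g <- conv_geometry(cur[1], cur[2], cur[3], row$k_h, row$k_w,
                           row$s_h, row$s_w, row$p_h, row$p_w)
        c_out <- row$maps
        fan_in <- g$ckk
        W <- matrix(stats::rnorm(c_out * g$ckk, sd = sqrt(2 / fan_in)),
                    nrow = c_out)
        b <- numeric(c_out)
        cur <- c(c_out, g$oh, g$ow)
        check(row, cur, length(W) + length(b))
        list(type = "conv", geom = g, c_out = c_out, W = W, b = b)
      },
      batchnorm = {
        check(row, cur, 0)
        list(type = "batchnorm", eps = 1e-5, momentum = 0.1,
             run_mean = numeric(cur[1]), run_var = rep(1, cur[1]))
      },
      activation = {
        check(row, cur, 0)
        list(type = "activation")
      },
      avgpool = {
        cur <- c(cur[1], cur[2] %/% row$k_h, cur[3] %/% row$k_w)
        check(row, cur, 0)
        list(type = "avgpool", k_h = row$k_h, k_w = row$k_w)
      },
      dropout = {
        check(row, cur, 0)
        list(type = "dropout", rate = row$dropout_rate)
      },
      flatten = {
        flat <- prod(cur)
        cur <- c(NA, NA, flat)
        check(row, cur, 0)
        list(type = "flatten", n = flat)
      },
      dense = {
        n_in <- cur[3]
        n_out <- row$out_w
        W <- matrix(stats::rnorm(n_out * n_in, sd = sqrt(2 / n_in)),
                    nrow = n_out)
        b <- numeric(n_out)
        cur <- c(NA, NA, n_out)
        check(row, cur, length(W) + length(b))
        list(type = "dense", W = W, b = b)
      },
      softmax = {
        check(row, cur, 0)
        list(type = "softmax")
      },
      stop("unknown layer type: ", row$type)
    )
    lyr$name <- row$layer
    layers[[row$layer]] <- lyr
  }
  structure(list(spec = spec, layers = layers, in_shape = in_shape,
                 classes = classes, seed = seed, history = NULL),
            class = "mi_cnn")
}

#' Per-layer trainable parameter counts
#'
#' @param model an `mi_cnn`.
#' @return Tibble: `layer`, `type`, `params`; attribute-free, computed from
#'   the realized weight arrays.
#' @export
model_param_counts <- function(model) {
  stopifnot(inherits(model, "mi_cnn"))
  purrr::map_dfr(model$layers, function(l) {
    tibble::tibble(layer = l$name, type = l$type,
                   params = if (!is.null(l$W)) length(l$W) + length(l$b) else 0L)
  })
}

#' Forward pass
#'
#' @param model an `mi_cnn`.
#' @param x input array `(channels, time, n)` or a single matrix.
#' @param train logical: training mode (batch statistics, dropout active).
#' @param keep_cache internal: retain intermediate activations.
#' @return List with `prob` (classes x n), per-layer `shapes`, and (when
#'   `keep_cache`) the activation `cache` for the backward pass.
#' @keywords internal
mi_cnn_forward <- function(model, x, train = FALSE, keep_cache = FALSE) {
  if (is.matrix(x)) x <- array(x, dim = c(dim(x), 1))
  n <- dim(x)[3]
  a <- array(x, dim = c(1, dim(x)[1], dim(x)[2], n))
  cache <- list()
  shapes <- list(input = dim(a))
  for (l in model$layers) {
    cache_entry <- NULL
    a <- switch(
      l$type,
      input = a,
      conv = {
        if (keep_cache) cache_entry <- list(x = a)
        conv_forward(l, a)
      },
      batchnorm = {
        f <- bn_forward(l, a, train)
        if (keep_cache) cache_entry <- f[c("xhat", "inv", "mu", "v")]
        f$y
      },
      activation = {
        y <- elu_forward(a)
        if (keep_cache) cache_entry <- list(y = y)
        y
      },
      avgpool = {
        if (keep_cache) cache_entry <- list(in_dim = dim(a))
        avgpool_forward(a, l$k_h, l$k_w)
      },
      dropout = {
        if (train) {
          mask <- spatial_dropout_mask(dim(a)[1], dim(a)[4], l$rate)
          if (keep_cache) cache_entry <- list(mask = mask)
          apply_channel_mask(a, mask)
        } else a
      },
      flatten = {
        matrix(a, nrow = l$n)
      },
      dense = {
        if (keep_cache) cache_entry <- list(x = a)
        l$W %*% a + l$b
      },
      softmax = softmax_rows(a)
    )
    if (keep_cache) cache[[l$name]] <- cache_entry
    shapes[[l$name]] <- dim(a)
  }
  list(prob = a, cache = cache, shapes = shapes)
}

#' Forward-pass shapes for one sample
#'
#' Runs a forward pass and returns the realized output shape after every
#' layer — the programmatic check of the layer table's size column.
#'
#' @param model an `mi_cnn`.
#' @return Tibble: `layer`, `shape` (printed as `maps x h x w`).
#' @export
model_shapes <- function(model) {
  x <- array(0, dim = c(model$in_shape, 1))
  out <- mi_cnn_forward(model, x, train = FALSE)
  purrr::imap_dfr(out$shapes, function(s, nm) {
    tibble::tibble(layer = nm,
                   shape = paste(utils::head(s, -1), collapse = "x"))
  })
}

#' @export
print.mi_cnn <- function(x, ...) {
  np <- sum(model_param_counts(x)$params)
  cat(sprintf("<mi_cnn> input %d x %d, %d trainable parameters%s\n",
              x$in_shape[1], x$in_shape[2], np,
              if (!is.null(x$history)) sprintf(", trained %d epochs (best test acc %.3f)",
                                               nrow(x$history),
                                               max(x$history$test_acc, na.rm = TRUE))
              else " (untrained)"))
  invisible(x)
}
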
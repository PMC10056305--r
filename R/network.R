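#' Layer constructors for network specifications
#'
#' A network specification is an ordered list of layer descriptions rich
#' enough for shape propagation, parameter counting, and instantiation.
#' `conv2d()` and `fully_connected()` carry weights; `maxpool2d()`,
#' `flatten()` and `dropout()` do not.
#'
#' @param in_channels,out_channels Channel counts (conv) or unit counts
#'   (fully connected).
#' @param kernel Square kernel extent `k` (conv/pool).
#' @param padding Zero padding per side, cells.
#' @param stride Step, cells.
#' @param activation One of `"relu"`, `"softmax"`, `"none"`.
#' @param p Drop probability in (0, 1).
#' @return A `layer_spec` list.
#' @name layer_spec
NULL

#' @rdname layer_spec
#' @export
conv2d <- function(in_channels, out_channels, kernel, padding = 0, stride = 1,
                   activation = "relu") {
  stopifnot(kernel >= 1, stride >= 1, padding >= 0)
  structure(list(kind = "conv2d", in_channels = in_channels,
                 out_channels = out_channels, kernel = kernel,
                 padding = padding, stride = stride,
                 activation = activation), class = "layer_spec")
}

#' @rdname layer_spec
#' @export
maxpool2d <- function(kernel, stride = kernel) {
  stopifnot(kernel >= 1, stride >= 1)
  structure(list(kind = "maxpool2d", kernel = kernel, padding = 0,
                 stride = stride, activation = "none"),
            class = "layer_spec")
}

#' @rdname layer_spec
#' @export
flatten <- function() {
  structure(list(kind = "flatten", activation = "none"), class = "layer_spec")
}

#' @rdname layer_spec
#' @export
fully_connected <- function(in_channels, out_channels, activation = "relu") {
  stopifnot(in_channels >= 1, out_channels >= 1)
  structure(list(kind = "fully_connected", in_channels = in_channels,
                 out_channels = out_channels, activation = activation),
            class = "layer_spec")
}

#' @rdname layer_spec
#' @export
dropout <- function(p = 0.5) {
  stopifnot(p > 0, p < 1)
  structure(list(kind = "dropout", p = p, activation = "none"),
            class = "layer_spec")
}

#' Construct a network specification
#'
#' @param layers List of `layer_spec` objects, in order.
#' @param input_shape Integer vector `c(height, width, channels)`.
#' @param num_classes Number of output classes.
#' @return A `network_spec`; construction fails if shapes do not
#'   propagate or the final layer is not a softmax over `num_classes`.
#' @export
network_spec <- function(layers, input_shape, num_classes) {
  stopifnot(length(input_shape) == 3, all(input_shape >= 1), num_classes >= 2)
  spec <- structure(list(layers = layers,
                         input_shape = as.integer(input_shape),
                         num_classes = as.integer(num_classes)),
                    class = "network_spec")
  shapes <- propagate_shapes(spec)
  final <- shapes[[length(shapes)]]
  if (length(final) != 1 || final != num_classes) {
    stop("final layer must output num_classes values")
  }
  wl <- spec$layers[[length(spec$layers)]]
  if (!identical(wl$activation, "softmax")) {
    stop("final layer must use a softmax activation")
  }
  spec
}

#' Spatial extent after a convolution or pooling layer
#'
#' Standard arithmetic `floor((n + 2p - k) / s) + 1`.
#'
#' @param n Input extent.
#' @param k Kernel extent.
#' @param p Padding per side.
#' @param s Stride.
#' @return Integer output extent.
#' @examples
#' conv_output_size(256, 12, 0, 4)  # 62
#' conv_output_size(32, 5, 0, 1)    # 28
#' @export
conv_output_size <- function(n, k, p = 0, s = 1) {
  stopifnot(s >= 1)
  if (k > n + 2 * p) stop("kernel exceeds padded input extent")
  as.integer(floor((n + 2 * p - k) / s) + 1)
}

#' Propagate shapes through a network specification
#'
#' @param spec A `network_spec`.
#' @return List with one element per layer: `c(height, width, channels)`
#'   for spatial layers, a single integer for flat layers.
#' @export
propagate_shapes <- function(spec) {
  stopifnot(inherits(spec, "network_spec"))
  shape <- spec$input_shape
  out <- vector("list", length(spec$layers))
  for (i in seq_along(spec$layers)) {
    l <- spec$layers[[i]]
    shape <- switch(
      l$kind,
      conv2d = {
        if (length(shape) != 3) stop("layer ", i, " (conv2d): input not spatial")
        if (shape[3] != l$in_channels) {
          stop("layer ", i, " (conv2d): expects ", l$in_channels,
               " channels, got ", shape[3])
        }
        c(conv_output_size(shape[1], l$kernel, l$padding, l$stride),
          conv_output_size(shape[2], l$kernel, l$padding, l$stride),
          l$out_channels)
      },
      maxpool2d = {
        if (length(shape) != 3) stop("layer ", i, " (maxpool2d): input not spatial")
        c(conv_output_size(shape[1], l$kernel, l$padding, l$stride),
          conv_output_size(shape[2], l$kernel, l$padding, l$stride),
          shape[3])
      },
      flatten = prod(shape),
      fully_connected = {
        if (length(shape) != 1) stop("layer ", i, " (fully_connected): input not flat")
        if (shape != l$in_channels) {
          stop("layer ", i, " (fully_connected): expects ", l$in_channels,
               " inputs, got ", shape)
        }
        l$out_channels
      },
      dropout = shape,
      stop("unknown layer kind: ", l$kind)
    )
    if (any(shape < 1)) {
      stop("layer ", i, " (", l$kind, "): non-positive output dimension")
    }
    out[[i]] <- as.integer(shape)
  }
  out
}

#' Count trainable parameters of a network specification
#'
#' Convolution layers contribute `k^2 * in_ch * out_ch + out_ch` (weights
#' plus biases), fully connected layers `in * out + out`; pooling,
#' flatten and dropout contribute nothing.
#'
#' @param spec A `network_spec`.
#' @return Total trainable parameter count (double to avoid integer
#'   overflow on large networks).
#' @export
count_parameters <- function(spec) {
  stopifnot(inherits(spec, "network_spec"))
  propagate_shapes(spec)  # validates wiring
  sum(vapply(spec$layers, function(l) {
    switch(l$kind,
           conv2d = l$kernel^2 * l$in_channels * l$out_channels +
             l$out_channels,
           fully_connected = l$in_channels * l$out_channels + l$out_channels,
           0)
  }, numeric(1)))
}

#' The original biometric network (256 x 256 portraits)
#'
#' An AlexNet-style feature extractor (five convolutional layers) and a
#' three-layer fully connected classifier with dropout 0.5 on both hidden
#' layers. With 115 classes the network holds 72,362,963 trainable
#' parameters. Designed for 256 x 256 x 1 binary portrait images.
#'
#' @param num_classes Number of individuals to identify (>= 2).
#' @return A `network_spec`.
#' @export
build_original_spec <- function(num_classes = 115) {
  if (num_classes < 2) stop("num_classes must be at least 2")
  network_spec(
    layers = list(
      conv2d(1, 96, kernel = 12, stride = 4),
      maxpool2d(2, stride = 2),
      conv2d(96, 256, kernel = 5, padding = 2),
      maxpool2d(3, stride = 2),
      conv2d(256, 384, kernel = 3, padding = 1),
      conv2d(384, 384, kernel = 3, padding = 1),
      conv2d(384, 256, kernel = 3, padding = 1),
      maxpool2d(3, stride = 2),
      flatten(),
      fully_connected(12544, 4096),
      dropout(0.5),
      fully_connected(4096, 4096),
      dropout(0.5),
      fully_connected(4096, num_classes, activation = "softmax")
    ),
    input_shape = c(256, 256, 1),
    num_classes = num_classes
  )
}

#' The scaled-down biometric network (32 x 32 portraits)
#'
#' Two small convolutional layers and the same classifier topology at
#' reduced width; with 115 classes it holds 6,711,251 trainable
#' parameters, roughly a tenfold reduction on the original network.
#' Designed for 32 x 32 x 1 portraits.
#'
#' @param num_classes Number of individuals to identify (>= 2).
#' @return A `network_spec`.
#' @export
build_scaled_spec <- function(num_classes = 115) {
  if (num_classes < 2) stop("num_classes must be at least 2")
  network_spec(
    layers = list(
      conv2d(1, 32, kernel = 5),
      maxpool2d(2, stride = 2),
      conv2d(32, 32, kernel = 2),
      flatten(),
      fully_connected(5408, 1024),
      dropout(0.5),
      fully_connected(1024, 1024),
      dropout(0.5),
      fully_connected(1024, num_classes, activation = "softmax")
    ),
    input_shape = c(32, 32, 1),
    num_classes = num_classes
  )
}

#' @export
print.network_spec <- function(x, ...) {
  shapes <- propagate_shapes(x)
  fmt <- function(s) paste(s, collapse = " x ")
  cat(sprintf("<network_spec> input %s, %d classes, %s parameters\n",
              fmt(x$input_shape), x$num_classes,
              format(count_parameters(x), big.mark = ",")))
  inp <- fmt(x$input_shape)
  for (i in seq_along(x$layers)) {
    l <- x$layers[[i]]
    extra <- switch(l$kind,
                    conv2d = sprintf(" k=%d p=%d s=%d", l$kernel, l$padding,
                                     l$stride),
                    maxpool2d = sprintf(" k=%d s=%d", l$kernel, l$stride),
                    dropout = sprintf(" p=%g", l$p),
                    "")
    cat(sprintf("  %2d %-16s %-14s -> %-14s%s\n", i, l$kind, inp,
                fmt(shapes[[i]]), extra))
    inp <- fmt(shapes[[i]])
  }
  invisible(x)
}

#' Serialize / deserialize a network specification
#'
#' @param spec A `network_spec`.
#' @param path File path for the JSON description.
#' @return `write_network_spec()` returns `path` invisibly;
#'   `read_network_spec()` returns the reconstructed `network_spec`.
#' @export
write_network_spec <- function(spec, path) {
  stopifnot(inherits(spec, "network_spec"))
  payload <- list(
    input_shape = spec$input_shape,
    num_classes = spec$num_classes,
    layers = purrr::map(spec$layers, ~ .x[setdiff(names(.x), NULL)])
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_network_spec
#' @export
read_network_spec <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE,
                                 simplifyDataFrame = FALSE)
  layers <- purrr::map(payload$layers, function(l) {
    switch(l$kind,
           conv2d = conv2d(l$in_channels, l$out_channels, l$kernel,
                           l$padding, l$stride, l$activation),
           maxpool2d = maxpool2d(l$kernel, l$stride),
           flatten = flatten(),
           fully_connected = fully_connected(l$in_channels, l$out_channels,
                                             l$activation),
           dropout = dropout(l$p),
           stop("unknown layer kind: ", l$kind))
  })
  network_spec(layers, unlist(payload$input_shape), payload$num_classes)
}
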
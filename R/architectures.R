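# Declarative network architectures, exact parameter accounting and the
# dilated-convolution receptive-field design rule.

layer <- function(kind, ...) {
  structure(c(list(kind = kind), list(...)), class = "layer_spec")
}

#' Layer constructors
#'
#' Build the declarative layer specifications a [model_spec()] is made of.
#' Sizes follow the conventions used throughout the package: recurrent `units`
#' are hidden units *per direction* (a BiLSTM therefore outputs `2 * units`
#' channels), `qkv_channels` is the total number of query/key/value channels
#' summed over attention heads, and `layer_add_skip(span)` closes a residual
#' block formed by the preceding `span` layers (optionally projecting the
#' block input with a kernel-1 convolution).
#'
#' @param channels,units,filters,kernel,dilation,heads,qkv_channels integer
#'   size parameters of the layer.
#' @param p dropout probability in (0, 1).
#' @param span number of preceding layers forming the residual branch.
#' @param skip_conv should the skip branch contain a kernel-1 convolution?
#' @param sequence_output does the recurrent layer emit one output per frame?
#' @return A `layer_spec` object (a named list).
#' @name layers
NULL

#' @rdname layers
#' @export
layer_input <- function(channels = 4L) {
  stopifnot(channels >= 1)
  layer("input", channels = as.integer(channels))
}

#' @rdname layers
#' @export
layer_bilstm <- function(units, sequence_output = TRUE) {
  stopifnot(units >= 1)
  layer("bilstm", units = as.integer(units), sequence_output = sequence_output)
}

#' @rdname layers
#' @export
layer_gru <- function(units, sequence_output = TRUE) {
  stopifnot(units >= 1)
  layer("gru", units = as.integer(units), sequence_output = sequence_output)
}

#' @rdname layers
#' @export
layer_dense <- function(units) {
  stopifnot(units >= 1)
  layer("dense", units = as.integer(units))
}

#' @rdname layers
#' @export
layer_dropout <- function(p) {
  if (!is.numeric(p) || p <= 0 || p >= 1) {
    abort("dropout probability must lie in (0, 1)", class = "gaitphase_config_error")
  }
  layer("dropout", p = p)
}

#' @rdname layers
#' @export
layer_spatial_dropout <- function(p) {
  if (!is.numeric(p) || p <= 0 || p >= 1) {
    abort("dropout probability must lie in (0, 1)", class = "gaitphase_config_error")
  }
  layer("spatial_dropout", p = p)
}

#' @rdname layers
#' @export
layer_sigmoid <- function() layer("sigmoid")

#' @rdname layers
#' @export
layer_relu <- function() layer("relu")

#' @rdname layers
#' @export
layer_softmax <- function() layer("softmax")

#' @rdname layers
#' @export
layer_conv1d <- function(filters, kernel, dilation = 1L) {
  stopifnot(filters >= 1, kernel >= 1, dilation >= 1)
  layer("conv1d", filters = as.integer(filters), kernel = as.integer(kernel),
        dilation = as.integer(dilation))
}

#' @rdname layers
#' @export
layer_layer_norm <- function() layer("layer_norm")

#' @rdname layers
#' @export
layer_add_skip <- function(span, skip_conv = FALSE) {
  stopifnot(span >= 1)
  layer("add_skip", span = as.integer(span), skip_conv = isTRUE(skip_conv))
}

#' @rdname layers
#' @export
layer_self_attention <- function(heads, qkv_channels) {
  stopifnot(heads >= 1, qkv_channels >= 1, qkv_channels %% heads == 0)
  layer("self_attention", heads = as.integer(heads),
        qkv_channels = as.integer(qkv_channels))
}

#' Create a model specification
#'
#' A `model_spec` is an ordered list of layers starting with an input layer
#' and ending with a 2-unit dense layer followed by a softmax, so that the
#' network emits per-frame stance/swing class probabilities. Both the exact
#' parameter accounting ([count_parameters()]) and the compiled network
#' instantiation derive from the same specification.
#'
#' @param name model name used in reports.
#' @param layers list of `layer_spec` objects.
#' @param hyperparams optional named list, e.g. `list(M = , P = )` for the
#'   pruned BiLSTM family.
#' @param tcn_params optional named list `list(N = , c = , b = , k = )` for
#'   dilated convolutional models.
#' @return A `model_spec` object.
#' @export
model_spec <- function(name, layers, hyperparams = NULL, tcn_params = NULL) {
  if (!length(layers) || layers[[1]]$kind != "input") {
    abort("a model_spec must start with an input layer", class = "gaitphase_spec_error")
  }
  n <- length(layers)
  if (n < 3 || layers[[n]]$kind != "softmax" || layers[[n - 1]]$kind != "dense" ||
      layers[[n - 1]]$units != 2L) {
    abort("a model_spec must end with dense(2) followed by softmax",
          class = "gaitphase_spec_error")
  }
  structure(list(name = name, layers = layers, hyperparams = hyperparams,
                 tcn_params = tcn_params),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("<model_spec> %s: %d layers, %s learnable parameters\n",
              x$name, length(x$layers),
              format(count_parameters(x), big.mark = ",")))
  invisible(x)
}

# channel width after each layer; element i is the width of layer i's output
layer_channels <- function(layers) {
  ch <- integer(length(layers))
  cur <- NA_integer_
  for (i in seq_along(layers)) {
    ly <- layers[[i]]
    cur <- switch(ly$kind,
      input = ly$channels,
      bilstm = 2L * ly$units,
      gru = ly$units,
      dense = ly$units,
      conv1d = ly$filters,
      # shape-preserving layers
      dropout = , spatial_dropout = , sigmoid = , relu = , softmax = ,
      layer_norm = , add_skip = , self_attention = cur,
      abort(paste0("unknown layer kind: ", ly$kind), class = "gaitphase_spec_error")
    )
    ch[i] <- cur
  }
  ch
}

#' Count learnable parameters of a model specification
#'
#' Sums the sizes of every learnable weight and bias array. Conventions:
#' BiLSTM per direction `4h(i+h) + 4h`; GRU `3h(i+h) + 3h` (one bias vector
#' per gate set); dense `h(i+1)`; conv1d `k * c_in * c_out + c_out`;
#' layer normalization `2 * channels`; self-attention
#' `3(D*i + D) + (i*D + i)` (query/key/value projections of the `i`-channel
#' stream into `D` total channels plus the output projection back to `i`);
#' dropout, activations and softmax contribute nothing. These conventions
#' reproduce the published counts of all five full architectures and of the
#' pruned BiLSTM family.
#'
#' @param spec a [model_spec()].
#' @return Integer-valued parameter total (as a double to avoid overflow).
#' @export
count_parameters <- function(spec) {
  stopifnot(inherits(spec, "model_spec"))
  layers <- spec$layers
  ch <- layer_channels(layers)
  total <- 0
  for (i in seq_along(layers)) {
    ly <- layers[[i]]
    inp <- if (i > 1) ch[i - 1] else NA_integer_
    total <- total + switch(ly$kind,
      input = 0,
      bilstm = {
        h <- ly$units
        2 * (4 * h * (inp + h) + 4 * h)
      },
      gru = {
        h <- ly$units
        3 * h * (inp + h) + 3 * h
      },
      dense = ly$units * (inp + 1),
      conv1d = ly$kernel * inp * ly$filters + ly$filters,
      layer_norm = 2 * inp,
      self_attention = {
        D <- ly$qkv_channels
        3 * (D * inp + D) + (inp * D + inp)
      },
      add_skip = {
        if (ly$skip_conv) {
          block_in <- ch[i - ly$span - 1L]
          1 * block_in * inp + inp
        } else 0
      },
      dropout = , spatial_dropout = , sigmoid = , relu = , softmax = 0,
      abort(paste0("unknown layer kind: ", ly$kind), class = "gaitphase_spec_error")
    )
  }
  total
}

#' Parameter storage footprint in bytes
#'
#' Assumes 32-bit storage of every learnable parameter, the format used when
#' exporting a model for deployment.
#'
#' @param spec a [model_spec()].
#' @return Number of bytes.
#' @export
memory_footprint <- function(spec) {
  4 * count_parameters(spec)
}

# truncate (not round) x to `digits` decimals; reporting convention for
# parameter counts in k/M units
trunc_decimal <- function(x, digits = 1) {
  trunc(x * 10^digits) / 10^digits
}

#' Display a parameter count the way architecture tables report it
#'
#' Counts at or above one million are shown in millions truncated to one
#' decimal ("1.2 M"); smaller counts in thousands truncated to one decimal
#' ("184.6 k"). Truncation, not rounding, is the convention.
#'
#' @param n parameter count.
#' @return A string such as `"1.2 M"`.
#' @export
format_parameter_count <- function(n) {
  if (n >= 1e6) {
    sprintf("%.1f M", trunc_decimal(n / 1e6, 1))
  } else {
    sprintf("%.1f k", trunc_decimal(n / 1e3, 1))
  }
}

#' Full BiLSTM reference architecture
#'
#' Four sequence-to-sequence BiLSTM layers with 200, 100, 100 and 100 hidden
#' units per direction, each followed by 60% dropout, then a fully connected
#' head of 100, 50 and 25 sigmoid units and the dense(2)+softmax classifier.
#' Totals 1,236,877 learnable parameters on 4 input channels.
#'
#' @return A [model_spec()].
#' @export
build_full_bilstm <- function() {
  model_spec("Full-BiLSTM", c(
    list(layer_input(4L)),
    unlist(lapply(c(200L, 100L, 100L, 100L), function(h) {
      list(layer_bilstm(h), layer_dropout(0.6))
    }), recursive = FALSE),
    list(layer_dense(100L), layer_sigmoid(),
         layer_dense(50L), layer_sigmoid(),
         layer_dense(25L), layer_sigmoid(),
         layer_dense(2L), layer_softmax())
  ))
}

#' Small BiLSTM architecture
#'
#' Two BiLSTM layers with 100 and 50 hidden units per direction, each followed
#' by 60% dropout, and the dense(2)+softmax classifier (184,602 parameters).
#'
#' @return A [model_spec()].
#' @export
build_small_bilstm <- function() {
  model_spec("Small-BiLSTM", list(
    layer_input(4L),
    layer_bilstm(100L), layer_dropout(0.6),
    layer_bilstm(50L), layer_dropout(0.6),
    layer_dense(2L), layer_softmax()
  ))
}

#' GRU architecture
#'
#' Two GRU layers with 100 and 50 units, each followed by 60% dropout, and the
#' dense(2)+softmax classifier (54,252 parameters).
#'
#' @return A [model_spec()].
#' @export
build_gru <- function() {
  model_spec("GRU", list(
    layer_input(4L),
    layer_gru(100L), layer_dropout(0.6),
    layer_gru(50L), layer_dropout(0.6),
    layer_dense(2L), layer_softmax()
  ))
}

#' Residual temporal convolutional network (Res-TCN)
#'
#' Three residual blocks of two dilated 1-D convolutions each (dilations 1, 2
#' and 4; `filters` channels; kernel length `k`), with layer normalization
#' after every convolution, 50% spatial dropout between the two convolutions,
#' and a ReLU after each residual addition. The first block's skip branch
#' carries a kernel-1 convolution to match channel counts. With `k = 37` and
#' 64 filters the network has 768,834 parameters and its receptive field
#' ([receptive_field()]) is the closest attainable to the 500-frame training
#' sequences.
#'
#' @param k convolutional kernel length.
#' @param filters convolutional filters per layer.
#' @return A [model_spec()].
#' @export
build_res_tcn <- function(k = 37L, filters = 64L) {
  stopifnot(k >= 1, filters >= 1)
  blocks <- unlist(lapply(1:3, function(j) {
    d <- 2L^(j - 1L)
    list(
      layer_conv1d(filters, k, dilation = d),
      layer_layer_norm(),
      layer_spatial_dropout(0.5),
      layer_conv1d(filters, k, dilation = d),
      layer_layer_norm(),
      layer_add_skip(span = 5L, skip_conv = (j == 1L)),
      layer_relu()
    )
  }), recursive = FALSE)
  model_spec("Res-TCN",
             c(list(layer_input(4L)), blocks,
               list(layer_dense(2L), layer_softmax())),
             tcn_params = list(N = 3L, c = 2L, b = 2L, k = as.integer(k)))
}

#' Multi-head self-attention architecture
#'
#' A 16-head self-attention block with 256 total query/key/value channels,
#' framed by layer normalization and by a dense(128)+ReLU+dropout(0.4) stack
#' on each side, then the dense(2)+softmax classifier (149,890 parameters, of
#' which the attention block holds 131,968).
#'
#' @return A [model_spec()].
#' @export
build_attention <- function() {
  model_spec("Attention", list(
    layer_input(4L),
    layer_dense(128L), layer_relu(), layer_dropout(0.4),
    layer_layer_norm(),
    layer_self_attention(heads = 16L, qkv_channels = 256L),
    layer_layer_norm(),
    layer_dense(128L), layer_relu(), layer_dropout(0.4),
    layer_dense(2L), layer_softmax()
  ))
}

#' Pruned BiLSTM family
#'
#' The two-hyperparameter architecture searched by the Bayesian optimizer: one
#' BiLSTM layer with `2P` hidden units per direction followed by two BiLSTM
#' layers with `P` units each (60% dropout after each), then fully connected
#' layers of `2M` and `M` sigmoid units (each followed by 60% dropout) and the
#' dense(2)+softmax classifier.
#'
#' @param M fully connected size hyperparameter, searched in \[15, 50\].
#' @param P recurrent size hyperparameter, searched in \[20, 100\].
#' @return A [model_spec()].
#' @export
build_pruned_bilstm <- function(M, P) {
  M <- as.integer(M); P <- as.integer(P)
  if (is.na(M) || is.na(P) || M < 1 || P < 1) {
    abort("M and P must be positive integers", class = "gaitphase_config_error")
  }
  if (M < 15 || M > 50 || P < 20 || P > 100) {
    warn(sprintf("(M=%d, P=%d) lies outside the search box M in [15,50], P in [20,100]",
                 M, P))
  }
  model_spec(sprintf("Pruned-BiLSTM[%d %d]", M, P), list(
    layer_input(4L),
    layer_bilstm(2L * P), layer_dropout(0.6),
    layer_bilstm(P), layer_dropout(0.6),
    layer_bilstm(P), layer_dropout(0.6),
    layer_dense(2L * M), layer_sigmoid(), layer_dropout(0.6),
    layer_dense(M), layer_sigmoid(), layer_dropout(0.6),
    layer_dense(2L), layer_softmax()
  ), hyperparams = list(M = M, P = P))
}

#' Receptive field of a dilated convolutional stack
#'
#' For `N` residual blocks of `c` stride-1 convolutional layers each, where
#' every layer of block `j` uses dilation `(b - 1) * b^(j-1)` (the standard
#' 1, 2, 4, ... schedule when the dilation basis is 2) and kernel length `k`,
#' one output frame depends on exactly `1 + c * (b^N - 1) * (k - 1)` input
#' frames. With the fixed design `c = 2`, `b = 2`, `N = 3`, `k = 37` this
#' gives 505 frames, the closest attainable to the 500-frame sequences.
#'
#' @param c convolutional layers per block.
#' @param b dilation basis.
#' @param N number of residual blocks.
#' @param k kernel length.
#' @return The receptive field in frames.
#' @export
receptive_field <- function(c, b, N, k) {
  stopifnot(c >= 1, b >= 1, N >= 1, k >= 1)
  1 + c * (b^N - 1) * (k - 1)
}

#' Choose the kernel length whose receptive field is closest to a target
#'
#' Scans integer kernel lengths and returns the one minimizing the absolute
#' difference between [receptive_field()] and `target`; ties break toward the
#' smaller kernel. With the fixed design `c = 2`, `b = 2`, `N = 3` and a
#' 500-frame target this selects `k = 37`.
#'
#' @param target desired receptive field (frames).
#' @inheritParams receptive_field
#' @param k_max largest kernel length scanned.
#' @return The selected integer kernel length.
#' @export
select_kernel <- function(target = 500L, c = 2L, b = 2L, N = 3L, k_max = 200L) {
  stopifnot(target >= 1)
  ks <- seq_len(k_max)
  err <- abs(vapply(ks, function(k) receptive_field(c, b, N, k), numeric(1)) - target)
  ks[which.min(err)]  # which.min takes the first (smallest k) on ties
}
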
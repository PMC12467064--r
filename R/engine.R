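# Bridge between declarative model specifications and the compiled network
# engine: spec compilation (with residual-block grouping), instantiation,
# prediction, and a portable plain-text checkpoint format.

# compile a model_spec into the nested list the engine consumes: every
# parameterized layer gets its input width, and each add_skip folds the
# preceding `span` layers into a residual block
compile_spec <- function(spec) {
  stopifnot(inherits(spec, "model_spec"))
  layers <- spec$layers
  ch <- layer_channels(layers)
  out <- list()
  for (i in seq_along(layers)) {
    ly <- layers[[i]]
    inp <- if (i > 1) ch[i - 1] else NA_integer_
    entry <- switch(ly$kind,
      input = NULL,
      dense = list(kind = "dense", units = ly$units, `in` = inp),
      bilstm = list(kind = "bilstm", units = ly$units, `in` = inp),
      gru = list(kind = "gru", units = ly$units, `in` = inp),
      conv1d = list(kind = "conv1d", filters = ly$filters, kernel = ly$kernel,
                    dilation = ly$dilation, `in` = inp),
      layer_norm = list(kind = "layer_norm", `in` = inp),
      self_attention = list(kind = "self_attention", heads = ly$heads,
                            qkv_channels = ly$qkv_channels, `in` = inp),
      dropout = list(kind = "dropout", p = ly$p),
      spatial_dropout = list(kind = "spatial_dropout", p = ly$p),
      sigmoid = list(kind = "sigmoid"),
      relu = list(kind = "relu"),
      softmax = list(kind = "softmax"),
      add_skip = {
        span <- ly$span
        if (span > length(out)) {
          abort("add_skip span exceeds preceding layer count",
                class = "gaitphase_spec_error")
        }
        inner <- out[(length(out) - span + 1L):length(out)]
        out <- out[seq_len(length(out) - span)]
        list(kind = "resblock", layers = inner,
             skip_conv = ly$skip_conv,
             `in` = ch[i - span - 1L], out = inp)
      },
      abort(paste0("unknown layer kind: ", ly$kind), class = "gaitphase_spec_error")
    )
    if (!is.null(entry)) out <- c(out, list(entry))
  }
  out
}

spec_is_trainable <- function(spec) {
  !any(vapply(spec$layers, function(l) l$kind == "self_attention", logical(1)))
}

#' Instantiate a network from its specification
#'
#' Builds the compiled network with freshly initialized weights (Glorot
#' uniform, forget-gate biases at 1), deterministically for a given seed.
#'
#' @param spec a [model_spec()].
#' @param seed integer seed for weight initialization.
#' @return A `gait_network` wrapping the engine handle.
#' @export
instantiate_network <- function(spec, seed = 1L) {
  ptr <- nn_build(compile_spec(spec), as.integer(seed))
  structure(list(spec = spec, ptr = ptr, seed = as.integer(seed)),
            class = "gait_network")
}

#' Trainable parameters of an instantiated network
#'
#' Counts the elements of every weight array held by the engine; used as the
#' independent cross-check of [count_parameters()], which derives the same
#' number from the declarative specification alone.
#'
#' @param net a `gait_network`.
#' @return Total number of trainable parameters.
#' @export
network_nparams <- function(net) {
  stopifnot(inherits(net, "gait_network"))
  nn_nparams(net$ptr)
}

#' Per-frame class probabilities for a batch of sequences
#'
#' @param net a `gait_network`.
#' @param x numeric array, either `N x C x T` (dataset layout) or `C x T` for
#'   a single window.
#' @return Array of probabilities in the same layout with 2 class channels.
#' @export
network_predict <- function(net, x) {
  stopifnot(inherits(net, "gait_network"))
  single <- length(dim(x)) == 2
  if (single) x <- array(x, dim = c(1L, dim(x)))
  p <- nn_forward(net$ptr, aperm(x, c(2, 1, 3)), FALSE)
  p <- aperm(p, c(2, 1, 3))
  if (single) p <- array(p, dim = dim(p)[-1]) else p
}

#' @export
print.gait_network <- function(x, ...) {
  cat(sprintf("<gait_network> %s: %s parameters (engine), seed %d\n",
              x$spec$name, format(network_nparams(x), big.mark = ","),
              x$seed))
  invisible(x)
}

# ---- plain-text checkpoint -------------------------------------------------

spec_to_list <- function(spec) {
  list(name = spec$name,
       layers = lapply(spec$layers, unclass),
       hyperparams = spec$hyperparams,
       tcn_params = spec$tcn_params)
}

list_to_spec <- function(lst) {
  layers <- lapply(lst$layers, function(l) {
    structure(lapply(l, function(v) {
      if (is.numeric(v) && length(v) == 1 && !is.logical(v) && v == round(v)) as.integer(v) else v
    }), class = "layer_spec")
  })
  model_spec(lst$name, layers, hyperparams = lst$hyperparams,
             tcn_params = lst$tcn_params)
}

#' Save a network to a portable text checkpoint
#'
#' Writes a directory holding `spec.json` (the declarative architecture) and
#' `weights.tsv` (every weight value in shortest-round-trip decimal form, one
#' row per element with its array name, row and column). The format is plain
#' text, diff-able, and loads back bit-identically; it is the package's model
#' interchange format, used by the streaming simulator to mirror a deployment
#' hand-off.
#'
#' @param net a `gait_network` (or the `network` field of a trained model).
#' @param path directory to create.
#' @return `path`, invisibly.
#' @export
save_network <- function(net, path) {
  stopifnot(inherits(net, "gait_network"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(spec_to_list(net$spec),
                       file.path(path, "spec.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  params <- nn_get_params(net$ptr)
  tab <- data.table::rbindlist(lapply(names(params), function(nm) {
    m <- params[[nm]]
    data.table::data.table(param = nm, row = as.vector(row(m)),
                           col = as.vector(col(m)), value = as.vector(m))
  }))
  fwrite_full(tab, file.path(path, "weights.tsv"))
  invisible(path)
}

#' Load a network from a text checkpoint
#'
#' @param path directory written by [save_network()].
#' @return A `gait_network` with the stored weights.
#' @export
load_network <- function(path) {
  spec_file <- file.path(path, "spec.json")
  if (!file.exists(spec_file)) {
    abort(sprintf("not a checkpoint directory (missing %s)", spec_file),
          class = "gaitphase_format_error")
  }
  spec <- list_to_spec(jsonlite::read_json(spec_file, simplifyVector = FALSE))
  net <- instantiate_network(spec, seed = 1L)
  tab <- data.table::fread(file.path(path, "weights.tsv"))
  params <- nn_get_params(net$ptr)
  for (nm in names(params)) {
    rows <- tab[tab$param == nm, ]
    if (nrow(rows) != length(params[[nm]])) {
      abort(sprintf("checkpoint weight table is inconsistent for %s", nm),
            class = "gaitphase_format_error")
    }
    m <- params[[nm]]
    m[cbind(rows$row, rows$col)] <- rows$value
    params[[nm]] <- m
  }
  nn_set_params(net$ptr, params)
  net
}
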
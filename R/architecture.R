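# Architecture strings and shape inference.
#
# Networks are declared in a compact semicolon-separated notation, e.g.
#   "Conv 32 5x5; Maxpool 3; Drop .8; Full 500; Drop .3; Output"
# Descriptors (case-insensitive):
#   Conv <n> <k>x<k>        tied convolution, n filters, "same" zero padding
#   Maxpool <w>[, stride s] max-pooling, window w; stride defaults to 2
#                           ("only every second pixel is recorded")
#   Drop <p>                dropout, fraction p of units zeroed per batch
#   Full [conn.] <n>        fully connected layer of n units
#   SUM                     residual sum of the two preceding stages
#   Output                  final layer, one unit per class, no nonlinearity

#' Built-in architecture presets
#'
#' The four reference architectures, verbatim in the layer-string notation.
#' \code{simpnet} is shallow (one conv, one dense); \code{deepnet} adds
#' convolutional depth; \code{deepernet} adds residual SUM stages;
#' \code{deepnet_s} is the variant used for untied locally connected runs.
#'
#' @return Named character vector of architecture strings.
#' @export
hebbnet_presets <- function() {
  c(simpnet = "Conv 32 5x5; Maxpool 3; Drop .8; Full 500; Drop .3; Output",
    deepnet = paste("Conv 32 5x5; Maxpool 3; Conv 32 3x3; Conv 32 3x3;",
                    "Maxpool 3; Drop .8; Conv 32 3x3; Conv 32 3x3;",
                    "Maxpool 3; Drop .3; Full 500; Output"),
    deepernet = paste("conv 16 3x3; conv 16 3x3; SUM; conv 32 3x3;",
                      "conv 32 3x3; SUM; maxpool 3; drop .5; conv 64 3x3;",
                      "conv 64 3x3; SUM; maxpool 3; conv 128 3x3;",
                      "conv 128 3x3; SUM; maxpool 3; drop .8;",
                      "full conn. 500; output"),
    deepnet_s = paste("conv 16 3x3; conv 16 3x3; SUM; maxpool 3, stride 3;",
                      "drop .5; conv 64 3x3; conv 64 3x3; SUM;",
                      "maxpool 2, stride 2; conv 64 2x2; conv 64 2x2; SUM;",
                      "maxpool 2, stride 2; drop .5; full conn. 500; output"))
}

parse_descriptor <- function(txt) {
  t <- tolower(trimws(txt))
  if (t == "sum") return(list(kind = "sum"))
  if (t == "output") return(list(kind = "output"))
  m <- regmatches(t, regexec("^conv[[:space:]]+([0-9]+)[[:space:]]+([0-9]+)x([0-9]+)$", t))[[1]]
  if (length(m)) return(list(kind = "conv", n = as.integer(m[2]),
                             kh = as.integer(m[3]), kw = as.integer(m[4])))
  m <- regmatches(t, regexec("^maxpool[[:space:]]+([0-9]+)([[:space:]]*,[[:space:]]*stride[[:space:]]+([0-9]+))?$", t))[[1]]
  if (length(m)) return(list(kind = "pool", window = as.integer(m[2]),
                             stride = if (nzchar(m[4])) as.integer(m[4]) else 2L))
  m <- regmatches(t, regexec("^drop[[:space:]]+(\\.?[0-9.]+)$", t))[[1]]
  if (length(m)) return(list(kind = "drop", rate = as.numeric(m[2])))
  m <- regmatches(t, regexec("^full([[:space:]]+conn\\.?)?[[:space:]]+([0-9]+)$", t))[[1]]
  if (length(m)) return(list(kind = "dense", n = as.integer(m[3])))
  stop("unknown layer descriptor: '", trimws(txt), "'")
}

#' Parse an architecture string into a network specification
#'
#' Resolves every stage's input and output shape for the given input
#' geometry and class count. Preset names (see [hebbnet_presets()]) are
#' accepted in place of a string.
#'
#' @param text Architecture string or preset name.
#' @param input_shape Integer \code{c(H, W, channels)} for image input, or a
#'   single integer for flat vector input.
#' @param n_classes Number of output classes \code{C}.
#' @param mode Training mode: \code{"bp"}, \code{"urfb"} or \code{"frfb"}.
#' @param sparsity Fraction of connections fixed at 0 (drawn independently
#'   for W and R, so connectivity itself is asymmetric).
#' @param loss \code{"hinge"} or \code{"softmax"}.
#' @param init Feedback initialization: \code{"independent"} (random,
#'   different from W) or \code{"mirrored"} (R = t(W), the exact-backprop
#'   case).
#' @param untied Realize convolutions as untied locally connected layers.
#' @return Object of class \code{"network_spec"}.
#' @export
parse_architecture <- function(text, input_shape, n_classes,
                               mode = c("urfb", "bp", "frfb"),
                               sparsity = 0, loss = c("hinge", "softmax"),
                               init = c("independent", "mirrored"),
                               untied = FALSE) {
  mode <- match.arg(mode); loss <- match.arg(loss); init <- match.arg(init)
  stopifnot(n_classes >= 2, sparsity >= 0, sparsity < 1)
  presets <- hebbnet_presets()
  if (length(text) == 1L && text %in% names(presets)) text <- presets[[text]]
  parts <- strsplit(text, ";", fixed = TRUE)[[1]]
  parts <- parts[nzchar(trimws(parts))]
  if (!length(parts)) stop("empty architecture string")
  descs <- lapply(parts, parse_descriptor)
  if (descs[[length(descs)]]$kind != "output")
    stop("architecture must end with an Output stage")
  shape <- as.integer(input_shape)       # length 3 (spatial) or 1 (flat)
  stages <- vector("list", length(descs))
  shapes <- vector("list", length(descs) + 1L)  # shapes[[s+1]] = out of s
  shapes[[1]] <- shape
  for (s in seq_along(descs)) {
    d <- descs[[s]]
    d$in_idx <- s - 1L
    d$in_shape <- shape
    if (d$kind == "conv") {
      if (length(shape) != 3L) stop("Conv stage ", s, " needs spatial input")
      if (untied) d$kind <- "local"
      d$geom <- conv_geometry(shape[1], shape[2], shape[3], d$n, d$kh, d$kw)
      shape <- c(shape[1], shape[2], d$n)
    } else if (d$kind == "pool") {
      if (length(shape) != 3L) stop("Maxpool stage ", s, " needs spatial input")
      shape <- c(length(seq.int(1L, shape[1], by = d$stride)),
                 length(seq.int(1L, shape[2], by = d$stride)), shape[3])
    } else if (d$kind == "drop") {
      # shape unchanged
    } else if (d$kind == "dense" || d$kind == "output") {
      d$n_in <- prod(shape)
      if (d$kind == "output") d$n <- as.integer(n_classes)
      shape <- d$n
    } else if (d$kind == "sum") {
      if (s < 3L) stop("SUM stage ", s, " has fewer than two preceding stages")
      a <- shapes[[s]]; b <- shapes[[s - 1L]]
      if (!identical(a, b))
        stop("SUM stage ", s, ": operand shapes differ (",
             paste(a, collapse = "x"), " vs ", paste(b, collapse = "x"), ")")
      d$in_idx2 <- s - 2L
    }
    d$out_shape <- shape
    stages[[s]] <- d
    shapes[[s + 1L]] <- shape
  }
  structure(list(stages = stages, input_shape = as.integer(input_shape),
                 n_classes = as.integer(n_classes), mode = mode,
                 sparsity = sparsity, loss = loss, init = init,
                 untied = untied, text = paste(trimws(parts), collapse = "; ")),
            class = "network_spec")
}

#' @export
print.network_spec <- function(x, ...) {
  cat("<network_spec> mode=", x$mode, " loss=", x$loss,
      " sparsity=", x$sparsity, " init=", x$init, "\n", sep = "")
  cat("  input: ", paste(x$input_shape, collapse = "x"),
      "  classes: ", x$n_classes, "\n", sep = "")
  for (s in seq_along(x$stages)) {
    st <- x$stages[[s]]
    cat(sprintf("  %2d %-7s -> %s\n", s, st$kind,
                paste(st$out_shape, collapse = "x")))
  }
  invisible(x)
}
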
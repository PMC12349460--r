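#' Architecture audit configuration
#'
#' Selects one of the five ablation variants of the lightweight
#' segmentation family and its audit conditions. `baseline` is the
#' YOLOv8n-seg reference; `starnet` swaps in the StarNet backbone;
#' `starnet_c2fstar` additionally replaces the neck's C2f bottlenecks with
#' Star blocks; `starnet_segmarigold` instead replaces the detection /
#' segmentation head with the shared group-normalized head; `full` applies
#' all three changes.
#'
#' All parameter counts reported by the audit are deployment-time counts:
#' batch normalization is folded into the preceding convolution (one bias
#' per conv), which is the convention lightweight-model tables in this
#' field report. Group normalization cannot be folded and keeps its 2C
#' affine parameters.
#'
#' @param variant one of `"baseline"`, `"starnet"`, `"starnet_c2fstar"`,
#'   `"starnet_segmarigold"`, `"full"`.
#' @param num_classes number of object classes (corolla, stem = 2).
#' @param input_size square input resolution, divisible by 32.
#' @param backbone_widths four StarNet stage widths; the stride-8/16/32
#'   stages feed the neck.
#' @param backbone_depths Star blocks per stage.
#' @param star_expansion channel expansion ratio inside a Star block's two
#'   parallel projection branches.
#' @return a list of class `arch_config`.
#' @export
arch_config <- function(variant = c("baseline", "starnet", "starnet_c2fstar",
                                    "starnet_segmarigold", "full"),
                        num_classes = 2,
                        input_size = 640,
                        backbone_widths = c(16, 32, 64, 160),
                        backbone_depths = c(1, 4, 6, 1),
                        star_expansion = 3) {
  variant <- match.arg(variant)
  stopifnot(
    input_size %% 32 == 0, num_classes >= 1,
    length(backbone_widths) == 4L, all(backbone_widths >= 1),
    length(backbone_depths) == 4L, all(backbone_depths >= 0),
    star_expansion >= 1
  )
  if (any(diff(backbone_widths) <= 0)) {
    stop("backbone widths must increase stage over stage", call. = FALSE)
  }
  structure(
    list(
      variant = variant,
      num_classes = as.integer(num_classes),
      input_size = as.integer(input_size),
      backbone_widths = as.integer(backbone_widths),
      backbone_depths = as.integer(backbone_depths),
      star_expansion = star_expansion
    ),
    class = "arch_config"
  )
}

# one audited layer; `stride` is the output stride relative to the input
# image, so FLOPs at input size S are 2 k^2 c1 c2 / g * (S/stride)^2.
layer_conv <- function(module, name, c_in, c_out, kernel, stride,
                       groups = 1, shared = FALSE, count_params = TRUE) {
  tibble::tibble(
    module = module, name = name, type = "conv",
    kernel = kernel, c_in = c_in, c_out = c_out, groups = groups,
    stride = stride,
    params = if (count_params) kernel^2 * c_in * c_out / groups + c_out else 0
  )
}

layer_norm <- function(module, name, channels) {
  tibble::tibble(
    module = module, name = name, type = "norm",
    kernel = 0, c_in = channels, c_out = channels, groups = 1, stride = 0,
    params = 2 * channels
  )
}

layer_scale <- function(module, name, n_params) {
  tibble::tibble(
    module = module, name = name, type = "scale",
    kernel = 0, c_in = 0, c_out = 0, groups = 1, stride = 0,
    params = n_params
  )
}

# distribution-focal decoding of box regression: a fixed-size 1x1 conv over
# reg_max bins applied to the 4 box sides at every anchor of each scale
layer_dfl <- function(reg_max) {
  dplyr::bind_rows(
    layer_conv("head", "dfl_p3", reg_max, 4, 1, 8, count_params = FALSE),
    layer_conv("head", "dfl_p4", reg_max, 4, 1, 16, count_params = FALSE),
    layer_conv("head", "dfl_p5", reg_max, 4, 1, 32, count_params = FALSE),
    layer_scale("head", "dfl_bins", reg_max)
  )
}

# ---- YOLOv8n-seg building blocks (fused Conv+BN = conv with bias) --------

conv_block <- function(module, name, c1, c2, k, stride) {
  layer_conv(module, name, c1, c2, k, stride)
}

c2f_block <- function(module, name, c1, c2, n, stride, star = FALSE,
                      expansion = 3) {
  c <- c2 %/% 2L
  rows <- list(conv_block(module, paste0(name, "_cv1"), c1, 2 * c, 1, stride))
  for (i in seq_len(n)) {
    bn <- paste0(name, "_b", i)
    if (star) {
      rows <- c(rows, list(
        layer_conv(module, paste0(bn, "_dw1"), c, c, 7, stride, groups = c),
        layer_conv(module, paste0(bn, "_f1"), c, expansion * c, 1, stride),
        layer_conv(module, paste0(bn, "_f2"), c, expansion * c, 1, stride),
        layer_conv(module, paste0(bn, "_g"), expansion * c, c, 1, stride),
        layer_conv(module, paste0(bn, "_dw2"), c, c, 7, stride, groups = c)
      ))
    } else {
      rows <- c(rows, list(
        conv_block(module, paste0(bn, "_cv1"), c, c, 3, stride),
        conv_block(module, paste0(bn, "_cv2"), c, c, 3, stride)
      ))
    }
  }
  rows <- c(rows, list(
    conv_block(module, paste0(name, "_cv2"), (2L + n) * c, c2, 1, stride)
  ))
  dplyr::bind_rows(rows)
}

sppf_block <- function(module, name, c1, c2, stride) {
  c_ <- c1 %/% 2L
  dplyr::bind_rows(
    conv_block(module, paste0(name, "_cv1"), c1, c_, 1, stride),
    conv_block(module, paste0(name, "_cv2"), 4L * c_, c2, 1, stride)
  )
}

# ---- backbones -----------------------------------------------------------

build_darknet_backbone <- function() {
  layers <- dplyr::bind_rows(
    conv_block("backbone", "conv0", 3, 16, 3, 2),
    conv_block("backbone", "conv1", 16, 32, 3, 4),
    c2f_block("backbone", "c2f2", 32, 32, 1, 4),
    conv_block("backbone", "conv3", 32, 64, 3, 8),
    c2f_block("backbone", "c2f4", 64, 64, 2, 8),
    conv_block("backbone", "conv5", 64, 128, 3, 16),
    c2f_block("backbone", "c2f6", 128, 128, 2, 16),
    conv_block("backbone", "conv7", 128, 256, 3, 32),
    c2f_block("backbone", "c2f8", 256, 256, 1, 32),
    sppf_block("backbone", "sppf9", 256, 256, 32)
  )
  attr(layers, "taps") <- c(64L, 128L, 256L)
  layers
}

star_block_rows <- function(module, name, c, stride, expansion, kernel = 3) {
  dplyr::bind_rows(
    layer_conv(module, paste0(name, "_dw1"), c, c, kernel, stride, groups = c),
    layer_conv(module, paste0(name, "_f1"), c, expansion * c, 1, stride),
    layer_conv(module, paste0(name, "_f2"), c, expansion * c, 1, stride),
    layer_conv(module, paste0(name, "_g"), expansion * c, c, 1, stride),
    layer_conv(module, paste0(name, "_dw2"), c, c, kernel, stride, groups = c)
  )
}

#' Build the StarNet backbone
#'
#' A stride-2 stem convolution followed by four stages. Each stage enters
#' through a depthwise-separable stride-2 downsampling unit (3x3 depthwise
#' + 1x1 pointwise) and then stacks Star blocks: a depthwise convolution,
#' two parallel 1x1 expansion branches fused by element-wise
#' multiplication, a 1x1 re-projection and a second depthwise convolution,
#' wrapped in a residual connection. The last three stage outputs (strides
#' 8, 16, 32) feed the neck.
#'
#' @param cfg an [arch_config()]; widths, depths and the expansion ratio
#'   come from it.
#' @return a layer tibble with a `taps` attribute naming the neck's input
#'   channels.
#' @export
build_starnet <- function(cfg = arch_config("starnet")) {
  w <- cfg$backbone_widths
  d <- cfg$backbone_depths
  rows <- list(conv_block("backbone", "stem", 3, w[1L], 3, 2))
  prev <- w[1L]
  for (s in 1:4) {
    stride <- 2L^(s + 1L)
    pre <- paste0("s", s)
    rows <- c(rows, list(
      layer_conv("backbone", paste0(pre, "_down_dw"), prev, prev, 3, stride,
                 groups = prev),
      layer_conv("backbone", paste0(pre, "_down_pw"), prev, w[s], 1, stride)
    ))
    for (b in seq_len(d[s])) {
      rows <- c(rows, list(
        star_block_rows("backbone", paste0(pre, "_star", b), w[s], stride,
                        cfg$star_expansion)
      ))
    }
    prev <- w[s]
  }
  layers <- dplyr::bind_rows(rows)
  attr(layers, "taps") <- w[2:4]
  layers
}

# ---- neck ----------------------------------------------------------------

#' Build a C2f-Star feature-fusion module
#'
#' The C2f split / transform / concatenate block with its bottlenecks
#' replaced by Star blocks (7x7 depthwise convolution, dual 1x1 expansion
#' branches with element-wise fusion, 1x1 re-projection, 7x7 depthwise,
#' residual). `n_blocks = 0` degenerates to the two projection
#' convolutions.
#'
#' @param in_ch,out_ch input and output channel counts.
#' @param n_blocks number of inner Star blocks.
#' @param stride output stride used for FLOP accounting (default 8).
#' @param expansion channel expansion ratio of the Star branches.
#' @return a layer tibble.
#' @export
build_c2f_star <- function(in_ch, out_ch, n_blocks = 1, stride = 8,
                           expansion = 3) {
  stopifnot(in_ch >= 1, out_ch >= 2)
  c2f_block("neck", "c2f_star", in_ch, out_ch, n_blocks, stride,
            star = TRUE, expansion = expansion)
}

build_neck <- function(taps, star = FALSE, expansion = 3) {
  t3 <- taps[1L]; t4 <- taps[2L]; t5 <- taps[3L]
  dplyr::bind_rows(
    c2f_block("neck", "c2f12", t5 + t4, 128, 1, 16, star, expansion),
    c2f_block("neck", "c2f15", 128 + t3, 64, 1, 8, star, expansion),
    conv_block("neck", "conv16", 64, 64, 3, 16),
    c2f_block("neck", "c2f18", 64 + 128, 128, 1, 16, star, expansion),
    conv_block("neck", "conv19", 128, 128, 3, 32),
    c2f_block("neck", "c2f21", 128 + t5, 256, 1, 32, star, expansion)
  )
}

# ---- heads ---------------------------------------------------------------

# standard YOLOv8-seg decoupled head + YOLACT-style prototype branch
build_seg_head <- function(ch = c(64, 128, 256), num_classes = 2) {
  reg_max <- 16L
  c2h <- max(16L, ch[1L] %/% 4L, 4L * reg_max)
  c3h <- max(ch[1L], min(num_classes, 100L))
  c4h <- max(ch[1L] %/% 4L, 32L)
  strides <- c(8L, 16L, 32L)
  rows <- list()
  for (i in 1:3) {
    s <- strides[i]; c <- ch[i]; tag <- paste0("p", i + 2L)
    rows <- c(rows, list(
      conv_block("head", paste0("cv2_", tag, "_0"), c, c2h, 3, s),
      conv_block("head", paste0("cv2_", tag, "_1"), c2h, c2h, 3, s),
      layer_conv("head", paste0("cv2_", tag, "_out"), c2h, 4L * reg_max, 1, s),
      conv_block("head", paste0("cv3_", tag, "_0"), c, c3h, 3, s),
      conv_block("head", paste0("cv3_", tag, "_1"), c3h, c3h, 3, s),
      layer_conv("head", paste0("cv3_", tag, "_out"), c3h, num_classes, 1, s),
      conv_block("head", paste0("cv4_", tag, "_0"), c, c4h, 3, s),
      conv_block("head", paste0("cv4_", tag, "_1"), c4h, c4h, 3, s),
      layer_conv("head", paste0("cv4_", tag, "_out"), c4h, 32, 1, s)
    ))
  }
  rows <- c(rows, list(
    layer_dfl(reg_max),
    conv_block("head", "proto_cv1", ch[1L], 64, 3, 8),
    layer_conv("head", "proto_up", 64, 64, 2, 4),   # 2x2 transposed conv
    conv_block("head", "proto_cv2", 64, 64, 3, 4),
    conv_block("head", "proto_cv3", 64, 32, 1, 4)
  ))
  dplyr::bind_rows(rows)
}

#' Build the shared group-normalized segmentation head
#'
#' A lightweight dual-path head. Per scale, a 1x1 convolution with group
#' normalization projects the neck output to a common width; a stack of
#' three 3x3 Conv-GN layers is then *shared* across the three scales
#' (parameters counted once, compute executed per scale) and feeds two
#' sibling 1x1 Conv-GN outputs: the detection path (distribution-focal box
#' regression over 8 bins plus class logits) and the mask-coefficient path
#' (32 coefficients). A learnable scalar Scale unit per scale and per
#' output branch (9 scalars) lets the shared stack adapt to each
#' resolution. The prototype-mask branch keeps the YOLACT-style design with
#' Conv-GN layers and a parameter-free 2x upsampling.
#'
#' @param in_channels the three per-scale input channel counts.
#' @param num_classes number of classes.
#' @return a layer tibble.
#' @export
build_seg_marigold_head <- function(in_channels = c(64, 128, 256),
                                    num_classes = 2) {
  stopifnot(length(in_channels) >= 1L)
  reg_max <- 8L
  c_proj <- 64L
  c_stack <- 72L
  n_mask <- 32L
  det_out <- 4L * reg_max + num_classes
  strides <- c(8L, 16L, 32L)[seq_along(in_channels)]
  rows <- list()
  for (i in seq_along(in_channels)) {
    s <- strides[i]; tag <- paste0("p", i + 2L)
    rows <- c(rows, list(
      layer_conv("head", paste0("proj_", tag), in_channels[i], c_proj, 1, s,
                 count_params = TRUE),
      layer_norm("head", paste0("proj_", tag, "_gn"), c_proj)
    ))
  }
  # shared Conv-GN stack: parameters once, compute at every scale
  shared <- function(name, c1, c2, k) {
    rows <- list()
    for (i in seq_along(strides)) {
      rows <- c(rows, list(
        layer_conv("head", paste0(name, "_p", i + 2L), c1, c2, k, strides[i],
                   count_params = (i == 1L))
      ))
    }
    rows[[1L]] <- dplyr::bind_rows(
      rows[[1L]],
      layer_norm("head", paste0(name, "_gn"), c2)
    )
    dplyr::bind_rows(rows)
  }
  rows <- c(rows, list(
    shared("stack1", c_proj, c_stack, 3),
    shared("stack2", c_stack, c_stack, 3),
    shared("stack3", c_stack, c_stack, 3),
    shared("det_out", c_stack, det_out, 1),
    shared("coef_out", c_stack, n_mask, 1),
    layer_dfl(reg_max),
    layer_scale("head", "scale_units", 3L * length(in_channels)),
    # prototype branch: Conv-GN, parameter-free 2x upsample, Conv-GN, 1x1
    layer_conv("head", "proto_cv1", 64, 64, 3, 8, count_params = TRUE),
    layer_norm("head", "proto_cv1_gn", 64),
    layer_conv("head", "proto_cv2", 64, 64, 3, 4),
    layer_norm("head", "proto_cv2_gn", 64),
    layer_conv("head", "proto_cv3", 64, n_mask, 1, 4),
    layer_norm("head", "proto_cv3_gn", n_mask)
  ))
  layers <- dplyr::bind_rows(rows)
  # GN replaces conv biases throughout this head
  layers$params[layers$type == "conv" & layers$params > 0] <-
    layers$params[layers$type == "conv" & layers$params > 0] -
    layers$c_out[layers$type == "conv" & layers$params > 0]
  layers
}

# ---- assembly ------------------------------------------------------------

#' Assemble an audit model
#'
#' Builds the layer graph of the requested ablation variant: backbone, neck
#' and head per the variant's row of the ablation grid.
#'
#' @param cfg an [arch_config()].
#' @return an object of class `scs_model`: the audited layer tibble plus
#'   the configuration and tap metadata.
#' @export
build_model <- function(cfg = arch_config()) {
  stopifnot(inherits(cfg, "arch_config"))
  backbone <- switch(cfg$variant,
    baseline = build_darknet_backbone(),
    build_starnet(cfg)
  )
  taps <- attr(backbone, "taps")
  star_neck <- cfg$variant %in% c("starnet_c2fstar", "full")
  marigold <- cfg$variant %in% c("starnet_segmarigold", "full")
  neck <- build_neck(taps, star = star_neck, expansion = cfg$star_expansion)
  head_in <- c(64L, 128L, 256L)
  head <- if (marigold) {
    build_seg_marigold_head(head_in, cfg$num_classes)
  } else {
    build_seg_head(head_in, cfg$num_classes)
  }
  structure(
    list(
      cfg = cfg,
      taps = taps,
      layers = dplyr::bind_rows(backbone, neck, head)
    ),
    class = "scs_model"
  )
}

#' @export
print.scs_model <- function(x, ...) {
  cat(sprintf(
    "<scs_model> variant '%s' (%d classes): %s parameters, %.1f GFLOPs @ %d\n",
    x$cfg$variant, x$cfg$num_classes,
    format(count_parameters(x), big.mark = ","),
    estimate_flops(x), x$cfg$input_size
  ))
  invisible(x)
}

#' Count trainable parameters
#'
#' Exact integer total over the model's layer graph, under the
#' deployment-fused convention described in [arch_config()]. Shared layers
#' are counted once.
#'
#' @param model an `scs_model` or a layer tibble.
#' @return parameter count (numeric, exact integer value).
#' @export
count_parameters <- function(model) {
  layers <- if (inherits(model, "scs_model")) model$layers else model
  sum(layers$params)
}

#' Analytic FLOP estimate
#'
#' Per-layer accounting at `input_size` x `input_size`: a convolution
#' contributes `2 k^2 c_in c_out H_out W_out / groups` (one multiply-add =
#' 2 operations); normalization, activation and element-wise fusion are not
#' counted. `convention = "macs"` reports multiply-accumulates instead
#' (half the FLOP figure).
#'
#' @param model an `scs_model` or layer tibble.
#' @param input_size square input resolution; defaults to the model's.
#' @param convention `"flops"` (multiply-add = 2) or `"macs"`.
#' @return giga-operations for one forward pass.
#' @export
estimate_flops <- function(model, input_size = NULL,
                           convention = c("flops", "macs")) {
  convention <- match.arg(convention)
  layers <- if (inherits(model, "scs_model")) model$layers else model
  if (is.null(input_size)) {
    input_size <- if (inherits(model, "scs_model")) model$cfg$input_size else 640L
  }
  stopifnot(input_size %% 32 == 0)
  conv <- layers[layers$type == "conv", , drop = FALSE]
  res <- (input_size / conv$stride)^2
  macs <- sum(conv$kernel^2 * conv$c_in * conv$c_out / conv$groups * res)
  (if (convention == "flops") 2 else 1) * macs / 1e9
}

#' Spatial shape audit of the layer graph
#'
#' Propagates the input resolution through every layer's output stride,
#' verifying the stride arithmetic end to end (a structural stand-in for a
#' forward pass: every audited layer must land on an integer spatial
#' size).
#'
#' @inheritParams estimate_flops
#' @return tibble of layers with `h_out` / `w_out` columns.
#' @export
model_shapes <- function(model, input_size = NULL) {
  layers <- if (inherits(model, "scs_model")) model$layers else model
  if (is.null(input_size)) {
    input_size <- if (inherits(model, "scs_model")) model$cfg$input_size else 640L
  }
  conv <- layers[layers$type == "conv", , drop = FALSE]
  sz <- input_size / conv$stride
  if (any(sz != round(sz))) {
    stop("non-integer feature-map size: stride arithmetic broken", call. = FALSE)
  }
  dplyr::mutate(conv, h_out = sz, w_out = sz)
}

#' Summarize an audited model
#'
#' Per-module parameter and FLOP breakdown plus totals, in the layout of a
#' complexity-comparison table row.
#'
#' @inheritParams estimate_flops
#' @return a tibble of class `model_summary` with one row per module and a
#'   `total` row.
#' @export
model_summary <- function(model, input_size = NULL) {
  layers <- if (inherits(model, "scs_model")) model$layers else model
  if (is.null(input_size)) {
    input_size <- if (inherits(model, "scs_model")) model$cfg$input_size else 640L
  }
  per <- dplyr::group_by(layers, .data$module)
  per <- dplyr::summarise(
    per,
    params = sum(.data$params),
    gflops = estimate_flops(dplyr::pick(dplyr::everything()), input_size),
    .groups = "drop"
  )
  out <- dplyr::bind_rows(
    per,
    tibble::tibble(
      module = "total",
      params = sum(per$params),
      gflops = sum(per$gflops)
    )
  )
  attr(out, "variant") <- if (inherits(model, "scs_model")) model$cfg$variant
  class(out) <- c("model_summary", class(out))
  out
}

#' @export
glance.scs_model <- function(x, ...) {
  tibble::tibble(
    variant = x$cfg$variant,
    num_classes = x$cfg$num_classes,
    input_size = x$cfg$input_size,
    total_params = count_parameters(x),
    gflops = estimate_flops(x),
    gmacs = estimate_flops(x, convention = "macs"),
    size_mb_fp16 = count_parameters(x) * 2 / 2^20
  )
}

#' @export
tidy.scs_model <- function(x, ...) {
  dplyr::select(
    x$layers, "module", "name", "type", "kernel",
    "c_in", "c_out", "groups", "stride", "params"
  )
}
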
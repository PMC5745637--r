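#' Informative-pixel attribution (DeepLIFT, rescale rule)
#'
#' Assigns each pixel (and channel) of a classified image-like array a
#' signed contribution to the difference between the prediction for the
#' input and the prediction for a reference input.  Contributions are
#' propagated backwards through the network: linearly at convolution and
#' dense layers, with the rescale rule (delta-output over delta-input) at
#' ReLU and sigmoid nonlinearities, and to the selected input location at
#' max-pooling layers.  Reference activations are computed through the
#' input's pooling switches, so the completeness property — contributions
#' summing to the output difference — holds to numerical precision.
#' Positive scores push the prediction towards binder (rendered red),
#' negative towards non-binder (blue).
#'
#' @name attribution
NULL

#' Compute a DeepLIFT attribution map for one encoded pair
#'
#' @param model An `ila_cnn` fit or an `ila_net`.
#' @param ila The `ila_array` to explain (must match the model input
#'   shape).
#' @param reference Reference `ila_array`, or `NULL` for the all-zero
#'   reference (which, because property scales are z-scored, is the
#'   mean amino-acid profile).
#' @return An `attribution_map`: `per_channel` (W x H x C signed scores),
#'   `per_pixel` (W x H channel sums), `actual_output`,
#'   `reference_output`, `peptide`, `allele`, `zero_diff` flag.
#' @export
deeplift_attribution <- function(model, ila, reference = NULL) {
  net <- if (inherits(model, "ila_cnn")) model$net else model
  stopifnot(inherits(net, "ila_net"), inherits(ila, "ila_array"))
  shape <- net$input_shape
  if (!identical(dim(ila$data), as.integer(shape)))
    stop(sprintf("ILA dims %s do not match model input %s",
                 paste(dim(ila$data), collapse = "x"),
                 paste(shape, collapse = "x")), call. = FALSE)
  x <- matrix(as.vector(ila$data), ncol = 1L)
  r <- if (is.null(reference)) x * 0 else {
    stopifnot(inherits(reference, "ila_array"))
    if (!identical(dim(reference$data), dim(ila$data)))
      stop("reference dims do not match input dims", call. = FALSE)
    matrix(as.vector(reference$data), ncol = 1L)
  }
  zero_diff <- max(abs(x - r)) == 0

  # Forward both inputs; the reference flows through the input's pooling
  # switches so every layer is linear or elementwise for the pair.
  ax <- x; ar <- r
  caches <- vector("list", length(net$layers))
  for (li in seq_along(net$layers)) {
    l <- net$layers[[li]]
    switch(l$type,
      conv = {
        caches[[li]] <- list(ax_in = ax)
        ax <- cpp_conv2d_fwd(ax, l$W, l$H, l$Cin, l$K, l$b)
        ar <- cpp_conv2d_fwd(ar, l$W, l$H, l$Cin, l$K, l$b)
      },
      relu = {
        caches[[li]] <- list(zx = ax, zr = ar)
        ax <- ax * (ax > 0); ar <- ar * (ar > 0)
      },
      pool = {
        fw <- cpp_maxpool2_fwd(ax, l$W, l$H, l$C)
        caches[[li]] <- list(idx = fw$idx)
        ax <- fw$y
        ar <- matrix(ar[as.vector(fw$idx) + 1L], ncol = 1L)
      },
      dropout = {},
      dense = {
        ax <- crossprod(l$Wt, ax) + l$b
        ar <- crossprod(l$Wt, ar) + l$b
      },
      sigmoid = {
        caches[[li]] <- list(zx = ax, zr = ar)
        ax <- stats::plogis(ax); ar <- stats::plogis(ar)
      },
      identity = {})
  }
  actual <- as.numeric(ax); ref_out <- as.numeric(ar)

  # Multiplier backward pass.
  m <- matrix(1, 1L, 1L)
  for (li in rev(seq_along(net$layers))) {
    l <- net$layers[[li]]
    switch(l$type,
      sigmoid = {
        zx <- caches[[li]]$zx; zr <- caches[[li]]$zr
        dz <- as.numeric(zx - zr)
        px <- stats::plogis(as.numeric(zx))
        fac <- if (abs(dz) > 1e-9)
          (px - stats::plogis(as.numeric(zr))) / dz else px * (1 - px)
        m <- m * fac
      },
      identity = {},
      dense = m <- l$Wt %*% m,
      relu = {
        zx <- caches[[li]]$zx; zr <- caches[[li]]$zr
        dz <- zx - zr
        ratio <- ifelse(abs(dz) > 1e-9,
                        (pmax(zx, 0) - pmax(zr, 0)) / dz,
                        (zx > 0) * 1)
        m <- m * ratio
      },
      pool = m <- cpp_maxpool2_bwd(m, caches[[li]]$idx, l$W, l$H, l$C),
      dropout = {},
      conv = m <- cpp_conv2d_bwd(caches[[li]]$ax_in, m, l$W, l$H, l$Cin,
                                 l$K, need_dx = TRUE, need_dw = FALSE)$dX)
  }
  per_channel <- array(as.vector(m) * as.vector(x - r), dim = shape)
  structure(list(per_channel = per_channel,
                 per_pixel = apply(per_channel, c(1L, 2L), sum),
                 actual_output = actual, reference_output = ref_out,
                 peptide = ila$peptide, allele = ila$allele,
                 zero_diff = zero_diff),
            class = "attribution_map")
}

#' Channel-summed per-pixel attribution
#'
#' @param attmap An `attribution_map`.
#' @return W x H signed matrix (positive = towards binder).
#' @export
aggregate_pixels <- function(attmap) {
  stopifnot(inherits(attmap, "attribution_map"))
  apply(attmap$per_channel, c(1L, 2L), sum)
}

#' Export an attribution map as a red/blue heatmap and CSV
#'
#' Writes `<prefix>.png` — a diverging red (binder) / blue (non-binder)
#' rendering with the colour range symmetric about zero and scaled to the
#' maximum absolute score — and `<prefix>.csv`, the same matrix with
#' 1-based peptide-position rows and contact-residue columns.
#'
#' @param map An `attribution_map` or a W x H signed matrix.
#' @param prefix Output path prefix.
#' @param pixel_size Integer magnification of each ILA pixel in the PNG.
#' @return Invisibly, the two file paths.
#' @export
export_heatmap <- function(map, prefix, pixel_size = 12L) {
  if (inherits(map, "attribution_map")) map <- map$per_pixel
  stopifnot(is.matrix(map))
  if (any(!is.finite(map))) stop("attribution map has non-finite values",
                                 call. = FALSE)
  disp <- t(map)                      # peptide positions as rows
  vmax <- max(abs(disp))
  v <- if (vmax > 0) disp / vmax else disp
  H <- nrow(v); W <- ncol(v)
  pos <- pmax(v, 0); neg <- pmax(-v, 0)
  rgb <- array(1, dim = c(H, W, 3L))
  rgb[, , 1] <- 1 - neg               # blue where negative
  rgb[, , 2] <- 1 - pos - neg
  rgb[, , 3] <- 1 - pos               # red where positive
  big <- rgb[rep(seq_len(H), each = pixel_size),
             rep(seq_len(W), each = pixel_size), , drop = FALSE]
  png_path <- paste0(prefix, ".png")
  csv_path <- paste0(prefix, ".csv")
  png::writePNG(big, png_path)
  dimnames(v) <- NULL
  out <- disp
  rownames(out) <- paste0("pos", seq_len(H))
  colnames(out) <- paste0("hla", seq_len(W))
  utils::write.csv(out, csv_path)
  invisible(c(png = png_path, csv = csv_path))
}

#' Read back a heatmap CSV written by [export_heatmap()]
#'
#' @param path Path to the CSV.
#' @return W x H matrix (contact residues x peptide positions).
#' @export
read_heatmap_csv <- function(path) {
  m <- as.matrix(utils::read.csv(path, row.names = 1L, check.names = FALSE))
  t(m)
}

#' @export
print.attribution_map <- function(x, ...) {
  d <- dim(x$per_channel)
  cat(sprintf("Attribution map for %s / %s (%dx%dx%d)\n",
              x$peptide %||% "<peptide>", x$allele %||% "<allele>",
              d[1L], d[2L], d[3L]))
  cat(sprintf("  output %.4f vs reference %.4f; total contribution %.4f%s\n",
              x$actual_output, x$reference_output,
              sum(x$per_channel),
              if (x$zero_diff) "  [input equals reference]" else ""))
  invisible(x)
}
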
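#' Appearance embeddings and re-identification plumbing
#'
#' Tracks carry a bounded gallery of appearance embeddings: 256-d real
#' vectors L2-normalised onto the unit hypersphere.  Association cost in
#' the cascade is the cosine distance
#' \deqn{d(A, B) = 1 - \frac{A \cdot B}{|A||B|}}
#' taken as the minimum over a track's gallery.  The embedding network
#' itself (a ResNet18 variant trained with triplet loss) is out of
#' scope; embeddings arrive from a sidecar file or from the
#' deterministic mock embedder used for synthetic runs.  A shape-plan
#' calculator validates layer tables of the re-identification
#' architecture.
#'
#' @name appearance
NULL

EMBED_DIM <- 256L

#' L2-normalise embedding vectors
#'
#' @param x an embedding vector, or a matrix of embeddings (one per row).
#' @return Input scaled to unit L2 norm (rows, for a matrix).
#' @export
l2_normalize <- function(x) {
  if (is.null(dim(x))) {
    n <- sqrt(sum(x^2))
    if (n == 0) stop("cannot normalise a zero vector")
    return(x / n)
  }
  n <- sqrt(rowSums(x^2))
  if (any(n == 0)) stop("cannot normalise a zero vector")
  x / n
}

#' Cosine distance between two embeddings
#'
#' `1 - cos(angle)`, in `[0, 2]`; invariant to the scale of either
#' vector.
#'
#' @param a,b nonzero numeric vectors of equal length.
#' @return A scalar in `[0, 2]`.
#' @export
cosine_distance <- function(a, b) {
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) stop("cosine distance undefined for zero vectors")
  d <- 1 - sum(a * b) / (na * nb)
  min(max(d, 0), 2)
}

#' Minimum cosine distance from a gallery to an embedding
#'
#' @param gallery matrix of gallery embeddings, one per row (non-empty).
#' @param e query embedding vector.
#' @return The minimum cosine distance over gallery members.
#' @export
gallery_distance <- function(gallery, e) {
  gallery <- as.matrix(gallery)
  if (nrow(gallery) == 0L) stop("gallery is empty")
  min(gallery_cost_matrix(gallery, matrix(e, nrow = 1L)))
}

# Min-over-gallery cosine cost of each query column: gallery (m x d),
# queries (n x d); returns length-n vector.  Both sides are normalised.
gallery_cost_matrix <- function(gallery, queries) {
  g <- l2_normalize(as.matrix(gallery))
  q <- l2_normalize(as.matrix(queries))
  sim <- g %*% t(q)
  1 - apply(sim, 2L, max)
}

#' Append an embedding to a bounded gallery
#'
#' Keeps insertion order; once `budget` is reached the oldest entries
#' are evicted first.
#'
#' @param gallery matrix of embeddings (possibly 0-row) or `NULL`.
#' @param e embedding to append.
#' @param budget maximum gallery size (default 100).
#' @return The updated gallery matrix.
#' @export
gallery_append <- function(gallery, e, budget = 100L) {
  e <- matrix(as.numeric(e), nrow = 1L)
  g <- if (is.null(gallery)) e else rbind(as.matrix(gallery), e)
  n <- nrow(g)
  if (n > budget) g <- g[(n - budget + 1L):n, , drop = FALSE]
  g
}

#' Deterministic mock embedding for a synthetic identity
#'
#' Each identity has a fixed anchor direction on the unit hypersphere,
#' derived reproducibly from the identity number alone (the global RNG
#' stream is untouched by anchor construction).  Gaussian perturbation
#' with standard deviation `noise_sigma` is added from the current RNG
#' stream and the result re-normalised; `noise_sigma = 0` returns the
#' anchor exactly.
#'
#' @param identity non-negative integer identity.
#' @param noise_sigma per-coordinate Gaussian noise sd (>= 0).
#' @param dim embedding dimension (default 256).
#' @return A unit-norm numeric vector of length `dim`.
#' @export
mock_embed <- function(identity, noise_sigma = 0, dim = EMBED_DIM) {
  if (identity < 0) stop("identity must be non-negative")
  if (noise_sigma < 0) stop("noise_sigma must be non-negative")
  anchor <- mock_anchor(identity, dim)
  if (noise_sigma == 0) return(anchor)
  l2_normalize(anchor + stats::rnorm(dim, 0, noise_sigma))
}

.anchor_cache <- new.env(parent = emptyenv())

mock_anchor <- function(identity, dim) {
  key <- paste(identity, dim)
  hit <- .anchor_cache[[key]]
  if (!is.null(hit)) return(hit)
  saved <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(saved)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", saved, envir = globalenv())
  })
  set.seed(1000003L + as.integer(identity) %% 1000000L)
  anchor <- l2_normalize(stats::rnorm(dim))
  .anchor_cache[[key]] <- anchor
  anchor
}

#' Layer specification for the shape planner
#'
#' @param name layer name.
#' @param kernel kernel size, scalar or `c(kh, kw)`; `NA` for adaptive
#'   average pooling.
#' @param stride integer stride >= 1.
#' @param out_channels output channel count.
#' @param type one of `"conv"`, `"pool"`, `"adaptive_avg_pool"`.
#' @return A `layer_spec` list.
#' @export
layer_spec <- function(name, kernel, stride, out_channels,
                       type = c("conv", "pool", "adaptive_avg_pool")) {
  type <- match.arg(type)
  if (type != "adaptive_avg_pool") {
    kernel <- rep(as.integer(kernel), length.out = 2L)
    if (any(kernel < 1L)) stop("kernel must be >= 1")
    if (as.integer(stride) < 1L) stop("stride must be >= 1")
  }
  structure(list(name = name, kernel = kernel, stride = as.integer(stride),
                 out_channels = as.integer(out_channels), type = type),
            class = "layer_spec")
}

#' Propagate feature-map shapes through a layer stack
#'
#' Spatial size follows `floor((s + 2p - k)/stride) + 1` with
#' "same"-style padding `p = k %/% 2` for convolution/pooling layers;
#' adaptive average pooling collapses the spatial dimensions to 1x1.
#'
#' @param layers list of [layer_spec()] objects.
#' @param input_shape input `c(channels, height, width)` (default
#'   `c(3, 256, 256)`).
#' @return A data.frame with one row per layer: `name`, `channels`,
#'   `height`, `width`.
#' @export
shape_plan <- function(layers, input_shape = c(3L, 256L, 256L)) {
  if (!length(layers)) stop("layer list is empty")
  ch <- input_shape[1L]; h <- input_shape[2L]; w <- input_shape[3L]
  out <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    ly <- layers[[i]]
    if (ly$type == "adaptive_avg_pool") {
      h <- 1L; w <- 1L
    } else {
      p <- ly$kernel %/% 2L
      h <- (h + 2L * p[1L] - ly$kernel[1L]) %/% ly$stride + 1L
      w <- (w + 2L * p[2L] - ly$kernel[2L]) %/% ly$stride + 1L
      if (h <= 0L || w <= 0L)
        stop("layer '", ly$name, "' collapses the feature map to non-positive size")
    }
    ch <- ly$out_channels
    out[[i]] <- data.frame(name = ly$name, channels = ch,
                           height = h, width = w,
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Layer table of the re-identification backbone
#'
#' The ResNet18-style embedding network used for cattle
#' re-identification: initial 7x7 stride-2 convolution, 3x3 stride-2
#' max pool, eight 3x3 residual blocks, adaptive average pooling, and a
#' 1x1 convolution down to the 256-d feature space.  The ninth residual
#' block runs at stride 1 (instead of the stock stride 2) so the final
#' stages keep a 16x16 feature map.
#'
#' @param residual9_stride stride of the ninth residual block (default
#'   1, the resolution-preserving modification; 2 gives the stock
#'   backbone).
#' @return A list of [layer_spec()] objects.
#' @export
resnet18_reid_layers <- function(residual9_stride = 1L) {
  list(
    layer_spec("Conv1 + BN + Relu", 7, 2, 64, "conv"),
    layer_spec("Max Pool 2",        3, 2, 64, "pool"),
    layer_spec("Residual 3",  3, 1, 64,  "conv"),
    layer_spec("Residual 4",  3, 1, 64,  "conv"),
    layer_spec("Residual 5",  3, 2, 128, "conv"),
    layer_spec("Residual 6",  3, 1, 128, "conv"),
    layer_spec("Residual 7",  3, 2, 256, "conv"),
    layer_spec("Residual 8",  3, 1, 256, "conv"),
    layer_spec("Residual 9",  3, residual9_stride, 512, "conv"),
    layer_spec("Residual 10", 3, 1, 512, "conv"),
    layer_spec("AdaptiveAvgPool 11", NA, 1, 512, "adaptive_avg_pool"),
    layer_spec("Conv 12", 1, 1, 256, "conv")
  )
}
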
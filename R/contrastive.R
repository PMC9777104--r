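# SimCLR-style contrastive pretraining of the encoder: a two-matrix
# projection head with ReLU, cosine similarity, the NT-Xent pair and batch
# losses with temperature tau, and the SGD pretraining loop.

#' Contrastive pretraining configuration
#'
#' Defaults follow the published training recipe: temperature 0.07, SGD
#' with learning rate 0.001 and momentum 0.9, 50 epochs, mini-batch 2.
#'
#' @param temperature Softmax temperature (> 0).
#' @param batch_size Images per mini-batch (each contributes two views).
#' @param epochs Training epochs.
#' @param lr Initial learning rate.
#' @param optimizer Only `"sgd"` is provided.
#' @param momentum SGD momentum.
#' @param projection_dim Output dimension of the projection head.
#' @param augment An [augment_config()] for view construction.
#' @param seed Integer run seed; fans out into init/augmentation/order
#'   sub-streams.
#' @return A `contrastive_config` list.
#' @export
contrastive_config <- function(temperature = 0.07, batch_size = 2L,
                               epochs = 50L, lr = 0.001,
                               optimizer = "sgd", momentum = 0.9,
                               projection_dim = 128L,
                               augment = augment_config(), seed = 1L) {
  if (temperature <= 0) stop("temperature must be > 0")
  if (batch_size < 1) stop("batch_size must be >= 1")
  structure(list(temperature = temperature, batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), lr = lr, optimizer = optimizer,
                 momentum = momentum, projection_dim = as.integer(projection_dim),
                 augment = augment, seed = as.integer(seed)),
            class = "contrastive_config")
}

#' Initialize the projection head
#'
#' Two weight matrices with a ReLU between them and no biases; the hidden
#' width defaults to the encoder output width.
#'
#' @param input_dim Encoder bottleneck dimension.
#' @param hidden_dim Hidden width.
#' @param output_dim Projection dimension (128 by default).
#' @param rng An [rng_stream()] or integer seed.
#' @return List with matrices `W1` (input x hidden) and `W2`
#'   (hidden x output).
#' @export
projection_init <- function(input_dim, hidden_dim = input_dim,
                            output_dim = 128L, rng = 1L) {
  if (!inherits(rng, "rng_stream")) rng <- rng_stream(rng)
  list(W1 = init_linear_w(rng, input_dim, hidden_dim),
       W2 = init_linear_w(rng, hidden_dim, output_dim))
}

#' Project a bottleneck vector into the contrastive space
#'
#' Computes `W2' relu(W1' v)`; no normalization is applied here (it lives
#' inside the cosine similarity).
#'
#' @param v Numeric vector (encoder bottleneck).
#' @param params From [projection_init()].
#' @return Numeric vector of length `ncol(params$W2)`.
#' @export
project <- function(v, params) {
  if (length(v) != nrow(params$W1)) {
    stop("projection head expects input of length ", nrow(params$W1),
         ", got ", length(v))
  }
  h <- pmax(as.vector(v %*% params$W1), 0)
  as.vector(h %*% params$W2)
}

nn_project <- function(g, v, p) {
  x <- ad_reshape(g, v, c(1L, length(v$value)))
  h <- ad_relu(g, ad_matmul(g, x, p$W1))
  out <- ad_matmul(g, h, p$W2)
  ad_reshape(g, out, ncol(out$value))
}

#' Cosine similarity
#'
#' @param a,b Nonzero numeric vectors of equal length.
#' @return A scalar in `[-1, 1]`.
#' @export
cosine_similarity <- function(a, b) {
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) stop("cosine similarity is undefined for a zero vector")
  sum(a * b) / (na * nb)
}

as_projection_matrix <- function(projections) {
  if (is.list(projections)) projections <- do.call(rbind, projections)
  if (!is.matrix(projections)) stop("projections must be a matrix or list of vectors")
  projections
}

#' NT-Xent loss for one directed pair
#'
#' `-log( exp(cos(R_i, R_j)/tau) / sum_{k != i} exp(cos(R_i, R_k)/tau) )`,
#' where the denominator runs over every other projection in the batch
#' (including the views of other images).
#'
#' @param i,j Indices of the anchor and its positive (1-based, `i != j`).
#' @param projections `2N x D` matrix (or list of vectors), views stored
#'   pair-adjacent.
#' @param temperature Softmax temperature.
#' @return Nonnegative scalar.
#' @export
ntxent_pair <- function(i, j, projections, temperature = 0.07) {
  P <- as_projection_matrix(projections)
  n <- nrow(P)
  if (n < 2) stop("need at least 2 projections")
  if (i == j) stop("i and j must differ")
  sims <- vapply(seq_len(n), function(k) {
    if (k == i) NA_real_ else cosine_similarity(P[i, ], P[k, ])
  }, numeric(1))
  num <- exp(sims[j] / temperature)
  den <- sum(exp(sims[-i] / temperature))
  -log(num / den)
}

#' NT-Xent loss over a batch of paired projections
#'
#' Mean of the two directed pair losses over all N pairs, Eq. form
#' `1/(2N) sum_k [ l(2k-1, 2k) + l(2k, 2k-1) ]`.
#'
#' @param projections `2N x D` matrix (or list), views pair-adjacent:
#'   rows (1,2) are the two views of image 1, and so on.
#' @param temperature Softmax temperature.
#' @return Nonnegative scalar.
#' @export
ntxent_batch <- function(projections, temperature = 0.07) {
  P <- as_projection_matrix(projections)
  n <- nrow(P)
  if (n %% 2L != 0L) stop("projections must come in pairs (even count)")
  total <- 0
  for (k in seq_len(n %/% 2L)) {
    total <- total + ntxent_pair(2L * k - 1L, 2L * k, P, temperature) +
      ntxent_pair(2L * k, 2L * k - 1L, P, temperature)
  }
  total / n
}

# Tape version over a list of projection nodes.
nn_cosine <- function(g, a, b) {
  num <- ad_sum(g, ad_mul(g, a, b))
  na <- ad_sqrt(g, ad_sum(g, ad_mul(g, a, a)))
  nb <- ad_sqrt(g, ad_sum(g, ad_mul(g, b, b)))
  ad_div(g, num, ad_mul(g, na, nb))
}

nn_ntxent_batch <- function(g, proj_nodes, temperature) {
  n <- length(proj_nodes)
  stopifnot(n %% 2L == 0L)
  # pairwise scaled similarities
  sim <- vector("list", n)
  for (i in seq_len(n)) sim[[i]] <- vector("list", n)
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      s <- ad_scale_const(g, nn_cosine(g, proj_nodes[[i]], proj_nodes[[j]]),
                          1 / temperature)
      sim[[i]][[j]] <- s
      sim[[j]][[i]] <- s
    }
  }
  directed <- function(i, j) {
    num <- sim[[i]][[j]]
    den <- NULL
    for (k in seq_len(n)) {
      if (k == i) next
      e <- ad_exp(g, sim[[i]][[k]])
      den <- if (is.null(den)) e else ad_add(g, den, e)
    }
    ad_sub(g, ad_log(g, den), num)
  }
  total <- NULL
  for (k in seq_len(n %/% 2L)) {
    l1 <- directed(2L * k - 1L, 2L * k)
    l2 <- directed(2L * k, 2L * k - 1L)
    s <- ad_add(g, l1, l2)
    total <- if (is.null(total)) s else ad_add(g, total, s)
  }
  ad_scale_const(g, total, 1 / n)
}

#' Contrastive pretraining of the encoder
#'
#' Trains the encoder plus projection head with the NT-Xent objective on
#' augmented view pairs. Writes a per-epoch loss log
#' (`pretrain_loss.csv`, columns `epoch,mean_loss`) and a rolling encoder
#' checkpoint at the end of every epoch.
#'
#' @param manifest A corpus manifest: data frame with an `image` column, or
#'   the path of a manifest CSV written by [generate_corpus()].
#' @param encoder_cfg An [encoder_config()].
#' @param cfg A [contrastive_config()].
#' @param out_dir Output directory for the loss log and checkpoint.
#' @return List with `checkpoint` (path), `loss_log` (data frame), and the
#'   final `params`.
#' @export
pretrain <- function(manifest, encoder_cfg, cfg = contrastive_config(),
                     out_dir = tempfile("pretrain")) {
  man <- read_manifest(manifest)
  if (nrow(man) == 0L) stop("corpus manifest is empty")
  if (cfg$batch_size < 8L) {
    message("note: batch_size ", cfg$batch_size,
            " gives only ", 2L * cfg$batch_size - 2L,
            " negatives per anchor; consider >= 8 if memory allows")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  imgs <- lapply(man$image, function(p) {
    img <- load_image(p)
    if (dim(img)[1] != encoder_cfg$input_size) {
      img <- resize_image(img, encoder_cfg$input_size)
    }
    img
  })
  init_rng <- rng_stream(derive_seed(cfg$seed, "init"))
  aug_rng <- rng_stream(derive_seed(cfg$seed, "augment"))
  order_rng <- rng_stream(derive_seed(cfg$seed, "order"))
  enc <- encoder_init(encoder_cfg, init_rng)
  head <- projection_init(encoder_cfg$stage_channels[5],
                          output_dim = cfg$projection_dim, rng = init_rng)
  params <- list(encoder = enc, head = head)
  opt <- opt_sgd(lr = cfg$lr, momentum = cfg$momentum)
  loss_log <- data.frame(epoch = integer(0), mean_loss = numeric(0))
  ckpt <- file.path(out_dir, "encoder.rds")
  n <- length(imgs)
  for (epoch in seq_len(cfg$epochs)) {
    ord <- rng_sample(order_rng, seq_len(n))
    batch_losses <- numeric(0)
    b <- 1L
    while (b <= n) {
      idx <- ord[b:min(b + cfg$batch_size - 1L, n)]
      g <- ad_graph()
      pn <- wrap_params(g, params)
      proj_nodes <- list()
      for (ii in idx) {
        pair <- make_contrastive_views(imgs[[ii]], cfg$augment, aug_rng)
        for (view in list(pair$view_i, pair$view_j)) {
          st <- nn_encode(g, ad_const(g, view), encoder_cfg, pn$encoder,
                          training = TRUE)
          proj_nodes[[length(proj_nodes) + 1L]] <-
            nn_project(g, st$bottleneck, pn$head)
        }
      }
      loss <- nn_ntxent_batch(g, proj_nodes, cfg$temperature)
      ad_backward(g, loss)
      params <- apply_gradients(params, ad_grads(g), opt)
      batch_losses <- c(batch_losses, loss$value)
      b <- b + cfg$batch_size
    }
    loss_log <- rbind(loss_log,
                      data.frame(epoch = epoch, mean_loss = mean(batch_losses)))
    utils::write.csv(loss_log, file.path(out_dir, "pretrain_loss.csv"),
                     row.names = FALSE)
    save_checkpoint(ckpt, "encoder", encoder_cfg, params$encoder,
                    extra = list(head = params$head,
                                 contrastive = unclass(cfg)[setdiff(names(cfg), "augment")]))
  }
  list(checkpoint = ckpt, loss_log = loss_log, params = params)
}
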
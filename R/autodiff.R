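# Minimal reverse-mode automatic differentiation on a define-by-run tape.
# Nodes are environments holding a value, an accumulated gradient, parent
# links and a backward closure; ad_backward() walks recorded ids in reverse.

ad_graph <- function() {
  g <- new.env(parent = emptyenv())
  g$nodes <- vector("list", 512L)
  g$n <- 0L
  g$leaves <- list()
  g
}

ad_new_node <- function(value, requires, backward = NULL) {
  n <- new.env(parent = emptyenv())
  n$value <- value
  n$grad <- NULL
  n$requires <- requires
  n$backward <- backward
  class(n) <- "ad_node"
  n
}

ad_record <- function(g, node) {
  g$n <- g$n + 1L
  if (g$n > length(g$nodes)) {
    g$nodes <- c(g$nodes, vector("list", length(g$nodes)))
  }
  g$nodes[[g$n]] <- node
  node$id <- g$n
  node
}

#' @noRd
ad_const <- function(g, x) ad_record(g, ad_new_node(x, FALSE))

ad_leaf <- function(g, x, name = NULL) {
  n <- ad_record(g, ad_new_node(x, TRUE))
  if (!is.null(name)) g$leaves[[name]] <- n
  n
}

# `backward` is a function(grad) that accumulates into parents via ad_acc().
# It is only retained when some ancestor leaf requires a gradient, so pure
# inference graphs store no closures (and none of their captured buffers).
ad_op <- function(g, value, parents, backward) {
  req <- FALSE
  for (p in parents) if (p$requires) { req <- TRUE; break }
  ad_record(g, ad_new_node(value, req, if (req) backward else NULL))
}

# Accumulate `grad` into `node`, reducing over broadcast if the node held a
# scalar that was combined with an array.
ad_acc <- function(node, grad) {
  if (!node$requires) return(invisible(NULL))
  if (length(node$value) == 1L && length(grad) > 1L) grad <- sum(grad)
  node$grad <- if (is.null(node$grad)) grad else node$grad + grad
  invisible(NULL)
}

ad_backward <- function(g, loss) {
  stopifnot(length(loss$value) == 1L)
  loss$grad <- 1
  for (id in seq.int(loss$id, 1L)) {
    nd <- g$nodes[[id]]
    if (!is.null(nd$backward) && !is.null(nd$grad)) nd$backward(nd$grad)
  }
  invisible(NULL)
}

# Gradients for all registered leaves, zeros where the loss did not reach.
ad_grads <- function(g) {
  lapply(g$leaves, function(nd) {
    if (is.null(nd$grad)) array(0, dim = dim_or_len(nd$value)) else nd$grad
  })
}

dim_or_len <- function(x) if (is.null(dim(x))) length(x) else dim(x)
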
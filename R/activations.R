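#' Activation functions used by the block library
#'
#' `hswish()` is the piecewise-linear "hard" approximation of `swish()`
#' built from ReLU6; it is cheap on edge hardware, bounded below by -3/8,
#' identical to the identity for `x >= 3` and zero for `x <= -3`.
#' `hsigmoid()` is the matching hard approximation of the logistic function
#' and is the gate used inside squeeze-and-excitation blocks.
#'
#' @param x numeric vector or array.
#' @return numeric object of the same shape as `x`.
#' @examples
#' hswish(c(-4, -3, 0, 1, 3, 5))
#' swish(0:2)
#' @export
hswish <- function(x) x * relu6(x + 3) / 6

#' @rdname hswish
#' @export
swish <- function(x) x * stats::plogis(x)

#' @rdname hswish
#' @export
hsigmoid <- function(x) relu6(x + 3) / 6

#' @rdname hswish
#' @export
relu6 <- function(x) pmin(pmax(x, 0), 6)

#' @rdname hswish
#' @export
relu <- function(x) pmax(x, 0)

# derivative helpers used by the backward pass; defined next to the
# activations so the pair stays in sync
hswish_grad <- function(x) {
  ifelse(x <= -3, 0, ifelse(x >= 3, 1, (2 * x + 3) / 6))
}

hsigmoid_grad <- function(x) ifelse(x > -3 & x < 3, 1 / 6, 0)

relu_grad <- function(x) as.numeric(x > 0)

sigmoid <- function(x) stats::plogis(x)

logit <- function(p) stats::qlogis(p)

activation_fn <- function(kind) {
  switch(kind,
    hswish = hswish, relu = relu, relu6 = relu6, swish = swish,
    hsigmoid = hsigmoid, identity = , linear = identity,
    stop("unknown activation kind: ", kind)
  )
}

activation_grad_fn <- function(kind) {
  switch(kind,
    hswish = hswish_grad, relu = relu_grad, hsigmoid = hsigmoid_grad,
    identity = , linear = function(x) 1,
    stop("no gradient registered for activation kind: ", kind)
  )
}
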
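# small shared fixtures, built in code

toy_tree3 <- function() ape::read.tree(text = "((t1:1,t2:1):1,t3:2);")

toy_model <- function(n = 3, ...) dec_model(n, name = "toy", ...)

# two-epoch stratification over a 3-area space: area 3 unavailable early
toy_epochs <- function(boundary = 4) {
  epoch_stratification(c(Inf, boundary), c(boundary, 0),
                       rbind(c(TRUE, TRUE, FALSE), c(TRUE, TRUE, TRUE)))
}

papua_tips <- function(tree, codes) {
  stats::setNames(as.list(codes), tree$tip.label)
}
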
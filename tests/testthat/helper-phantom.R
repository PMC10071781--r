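# Shared template assets (48^3) built once per test run.
shared_template <- local({
  tmpl <- NULL
  function() {
    if (is.null(tmpl)) tmpl <<- make_template(c(48, 48, 48), seed = 42)
    tmpl
  }
})

dice_overlap <- function(a, b) {
  a <- as.logical(a); b <- as.logical(b)
  2 * sum(a & b) / (sum(a) + sum(b))
}
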
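# write lines to a tempfile owned by the calling test
withr_local_file <- function(lines, envir = parent.frame()) {
  p <- tempfile()
  writeLines(lines, p)
  withr::defer(unlink(p), envir = envir)
  p
}
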
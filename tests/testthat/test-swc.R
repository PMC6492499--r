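swc_text <- function(lines) {
  path <- withr::local_tempfile(fileext = ".swc", .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

test_that("a minimal well-formed SWC file parses into a 3-node chain", {
  path <- swc_text(c("# comment", "1 2 0 0 0 0.5 -1", "2 2 1 0 0 0.5 1",
                     "3 2 2 0 0 0.5 2"))
  sk <- read_swc(path)
  expect_s3_class(sk, "neuron_skeleton")
  expect_equal(nrow(sk), 3L)
  expect_equal(sum(sk$parent < 0), 1L)
  expect_equal(sk$x, c(0, 1, 2))
})

test_that("structural and parse errors are reported with context", {
  bad_parent <- swc_text(c("1 2 0 0 0 0.5 -1", "2 2 1 0 0 0.5 99"))
  expect_error(read_swc(bad_parent), "dangling parent")
  short_line <- swc_text(c("1 2 0 0 0 0.5 -1", "2 2 1 0"))
  expect_error(read_swc(short_line), "line 2")
  dup <- swc_text(c("1 2 0 0 0 0.5 -1", "1 2 1 0 0 0.5 1"))
  expect_error(read_swc(dup), "duplicate")
})

test_that("write_swc followed by read_swc reproduces the node table", {
  sk <- straight_skeleton(20)
  path <- withr::local_tempfile(fileext = ".swc")
  write_swc(sk, path)
  back <- read_swc(path)
  expect_equal(as.data.frame(back), as.data.frame(sk))
})

test_that("unit_scale converts coordinates to micrometres", {
  path <- swc_text("1 2 1000 2000 0 250 -1")
  sk <- read_swc(path, unit_scale = 1e-3)
  expect_equal(c(sk$x, sk$y, sk$radius), c(1, 2, 0.25))
})
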
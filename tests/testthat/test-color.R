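test_that("default bounds are symmetric about zero", {
  expect_equal(unname(ov_default_continuous_bounds(c(-3, 5))), c(-5, 0, 5))
  expect_equal(unname(ov_default_continuous_bounds(c(2, 4))), c(-4, 0, 4))
  expect_equal(unname(ov_default_continuous_bounds(-7)), c(-7, 0, 7))
  expect_error(ov_default_continuous_bounds(c(NA_real_, NA_real_)),
               class = "ovglyph_bounds_error")
  expect_error(ov_default_continuous_bounds(c(0, 0)),
               class = "ovglyph_bounds_error")
  withr::with_seed(9, {
    for (rep in 1:50) {
      v <- stats::rnorm(sample(1:20, 1), mean = stats::rnorm(1, 0, 3))
      b <- ov_default_continuous_bounds(v)
      expect_identical(b[["min"]], -b[["max"]])
      expect_identical(b[["mid"]], 0)
      expect_gte(b[["max"]], max(abs(v)))
    }
  })
})

test_that("continuous colors hit anchors exactly and clamp outside", {
  m <- ov_continuous_mapping(-8, 0, 8, "#0000FF", "#FFFFFF", "#FF0000")
  expect_identical(ov_continuous_color(0, m), "#FFFFFF")      # mid bit-exact
  expect_identical(ov_continuous_color(-8, m), "#0000FF")
  expect_identical(ov_continuous_color(8, m), "#FF0000")
  expect_identical(ov_continuous_color(-108, m), "#0000FF")   # clamp below
  expect_identical(ov_continuous_color(1e9, m), "#FF0000")    # clamp above
  # halfway up the upper segment: channel-wise 50% blend of white and red
  expect_identical(ov_continuous_color(4, m), oracle_lerp("#FFFFFF", "#FF0000", 0.5))
  expect_identical(ov_continuous_color(4, m), "#FF8080")
  # missing values take the designated missing color
  expect_identical(ov_continuous_color(NA, m), "#CCCCCC")
  expect_identical(ov_continuous_color(NA, m, na_color = "#123456"), "#123456")
})

test_that("interpolation agrees with an independent channel lerp", {
  withr::with_seed(21, {
    for (rep in 1:30) {
      anchors <- sort(stats::rnorm(3, 0, 5))
      cols <- toupper(sprintf("#%06X", sample.int(16777215, 3)))
      m <- ov_continuous_mapping(anchors[1], anchors[2], anchors[3],
                                 cols[1], cols[2], cols[3])
      v <- stats::runif(1, anchors[1], anchors[3])
      want <- if (v == anchors[2]) cols[2]
        else if (v < anchors[2]) {
          oracle_lerp(cols[1], cols[2],
                      (v - anchors[1]) / (anchors[2] - anchors[1]))
        } else {
          oracle_lerp(cols[2], cols[3],
                      (v - anchors[2]) / (anchors[3] - anchors[2]))
        }
      expect_identical(ov_continuous_color(v, m), want)
    }
  })
})

test_that("continuous colors are clamped and monotone per channel", {
  channels <- function(colors) t(grDevices::col2rgb(colors))
  withr::with_seed(77, {
    for (rep in 1:20) {
      a <- sort(stats::rnorm(3, 0, 4))
      if (a[1] == a[2] || a[2] == a[3]) next
      cols <- toupper(sprintf("#%06X", sample.int(16777215, 3)))
      m <- ov_continuous_mapping(a[1], a[2], a[3], cols[1], cols[2], cols[3])
      v <- stats::rnorm(40, 0, 6)
      clamped <- pmin(pmax(v, a[1]), a[3])
      expect_identical(ov_continuous_color(v, m),
                       ov_continuous_color(clamped, m))
      for (seg in list(seq(a[1], a[2], length.out = 12),
                       seq(a[2], a[3], length.out = 12))) {
        ch <- channels(ov_continuous_color(seg, m))
        for (j in 1:3) {
          d <- diff(ch[, j])
          expect_true(all(d >= 0) || all(d <= 0))
        }
      }
    }
  })
})

test_that("degenerate segments collapse to their shared anchor color", {
  m <- ov_continuous_mapping(0, 0, 4, "#000000", "#111111", "#222222")
  expect_identical(ov_continuous_color(0, m), "#000000")  # clamp wins at min
  expect_identical(ov_continuous_color(2, m), oracle_lerp("#111111", "#222222", 0.5))
  expect_error(ov_continuous_mapping(1, 0, 4), class = "ovglyph_input_error")
})

test_that("centering shifts values and bounds by the middle anchor", {
  m0 <- ov_continuous_mapping(-8, 0, 8)
  ct0 <- ov_center_transform(c(-3, 0, 5), m0)
  expect_identical(ct0$values, c(-3, 0, 5))               # mid 0: identity
  m <- ov_continuous_mapping(1, 2, 3)
  ct <- ov_center_transform(c(1, 2, 3), m)
  expect_identical(ct$values, c(-1, 0, 1))
  expect_identical(c(ct$min, ct$max), c(-1, 1))
  # composing with a zero-anchored colorer reproduces the original colors
  withr::with_seed(13, {
    for (rep in 1:20) {
      a <- sort(stats::rnorm(3, 1, 4))
      m <- ov_continuous_mapping(a[1], a[2], a[3])
      v <- stats::rnorm(15, 1, 5)
      ct <- ov_center_transform(v, m)
      m_zero <- ov_continuous_mapping(ct$min, 0, ct$max,
                                      m$min_color, m$mid_color, m$max_color)
      expect_identical(ov_continuous_color(v, m),
                       ov_continuous_color(ct$values, m_zero))
      # order-preserving and invertible given the middle value
      expect_identical(order(ct$values), order(v))
      expect_equal(ct$values + a[2], v)
    }
  })
})

test_that("discrete mapping strings parse in order and reject duplicates", {
  dm <- ov_parse_discrete_mapping("A:#1F78B4,B:#FF7F00,C:#E31A1C")
  expect_identical(dm$assignments$value, c("A", "B", "C"))
  expect_identical(dm$assignments$color, c("#1F78B4", "#FF7F00", "#E31A1C"))
  one <- ov_parse_discrete_mapping("X:#000000")
  expect_identical(nrow(one$assignments), 1L)
  expect_error(ov_parse_discrete_mapping("A:#1F78B4,A:#FF7F00"),
               regexp = "duplicate", class = "ovglyph_parse_error")
  expect_error(ov_parse_discrete_mapping("A:#12345"),
               class = "ovglyph_parse_error")
  expect_error(ov_parse_discrete_mapping("A-#123456"),
               class = "ovglyph_parse_error")
})

test_that("automatic discrete mappings follow first appearance and cycle", {
  dm <- ov_auto_discrete_mapping(c("b", "a", "b", "c"), palette = "Paired")
  expect_identical(dm$assignments$value, c("b", "a", "c"))
  expect_identical(dm$assignments$color, ov_palette("Paired")[1:3])
  expect_identical(nrow(ov_auto_discrete_mapping(character())$assignments), 0L)
  expect_warning(
    big <- ov_auto_discrete_mapping(sprintf("v%02d", 1:15), palette = "Paired"),
    regexp = "cycle")
  expect_identical(big$assignments$color[13], ov_palette("Paired")[1])
  # values absent from a mapping fall back to the missing color
  expect_identical(ovglyph:::ov_map_colors(c("a", "zz"), dm),
                   c(dm$assignments$color[2], "#CCCCCC"))
})
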
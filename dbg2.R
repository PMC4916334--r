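library(walkcounts)
# jsonlite with I(17)
x <- c(0.3794161658247299784, pi/7, 1e-17, 123456.789)
tmp <- tempfile(); jsonlite::write_json(list(v=x), tmp, digits=I(17))
cat(readLines(tmp),"\n")
cat("identical:", identical(jsonlite::read_json(tmp, simplifyVector=TRUE)$v, x), "\n")

# energy error line 47
set.seed(5)
x <- data.frame(activity_counts = runif(20, 3000, 9000))
pal2 <- 1.2 + 8e-5*x$activity_counts + rnorm(20,0,0.1)
x2 <- data.frame(a = x$activity_counts, b = x$activity_counts*(1+rnorm(20,0,1e-9)))
r <- tryCatch(fit_pal_model(pal2, x2), error=function(e) conditionMessage(e), warning=function(w) paste("WARN:",conditionMessage(w)))
print(r)

# template noise cancel
cyc <- sin(2*pi*(0:66)/67); cyc <- cyc - mean(cyc)
set.seed(4); noise <- rnorm(67,0,0.05)
tm2 <- build_template(list(cyc+noise, cyc-noise))
cat("max dev:", max(abs(tm2$waveform-cyc)), "\n")
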
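# JSON interface shared by the command line and the REST service.
#
# Both entry points call ground_json(), so their outputs are byte-identical
# for identical inputs.

#' Ground an entity string to JSON
#'
#' Runs [ground()] and renders the matches as a minified JSON array of
#' `{term: {namespace, id, text, status, standard_name, organism}, score,
#' variant_used}` objects.  Output is deterministic: fixed key order, scores
#' with up to 10 significant digits.
#'
#' @inheritParams ground
#' @return A JSON string.
#' @export
ground_json <- function(index, text, context = NULL, organisms = NULL,
                        models = NULL) {
  matches <- ground(index, text, context = context, organisms = organisms,
                    models = models)
  matches_to_json(matches)
}

matches_to_json <- function(matches) {
  items <- lapply(seq_len(nrow(matches)), function(i) {
    m <- matches[i, ]
    term <- list(namespace = m$namespace, id = m$identifier, text = m$text,
                 status = m$status, standard_name = m$standard_name)
    if (!is.na(m$organism)) term$organism <- m$organism
    out <- list(term = term, score = round(m$score, 10),
                variant_used = m$variant_used)
    if (!is.na(m$disamb_probability)) {
      out$disamb_probability <- round(m$disamb_probability, 10)
    }
    out
  })
  as.character(jsonlite::toJSON(items, auto_unbox = TRUE, digits = 10))
}

# -- request handler ----------------------------------------------------------

#' Handle one REST request
#'
#' Pure request router backing [serve()]: `POST /ground` takes a JSON body
#' `{text, context?, organisms?}` and returns the [ground_json()] result;
#' `GET /models` lists the canonical entity strings with a deployed
#' disambiguation model.  Errors come back as a JSON payload with an
#' `error` field and an HTTP-style status code.
#'
#' @param method,path HTTP method and path.
#' @param body Raw request body (JSON string; may be empty).
#' @param index A `grounding_index`.
#' @param models Optional disambiguator registry.
#' @param max_body Maximum accepted body size in bytes.
#' @return A list with `status` (integer) and `body` (JSON string).
#' @export
handle_request <- function(method, path, body, index, models = NULL,
                           max_body = 1e6) {
  err <- function(status, msg) {
    list(status = as.integer(status),
         body = as.character(jsonlite::toJSON(list(error = msg),
                                              auto_unbox = TRUE)))
  }
  if (nchar(body, type = "bytes") > max_body) {
    return(err(413L, paste0("request body exceeds ", max_body, " bytes")))
  }
  if (method == "GET" && path == "/models") {
    keys <- if (is.null(models)) character(0) else names(model_registry(models))
    return(list(status = 200L,
                body = as.character(jsonlite::toJSON(sort(keys)))))
  }
  if (method == "POST" && path == "/ground") {
    req <- tryCatch(jsonlite::fromJSON(body, simplifyVector = TRUE),
                    error = function(e) NULL)
    if (!is.list(req)) return(err(400L, "body must be a JSON object"))
    if (is.null(req$text) || !nzchar(req$text)) {
      return(err(400L, "missing required field: text"))
    }
    json <- tryCatch(
      suppressMessages(ground_json(index, req$text, context = req$context,
                                   organisms = req$organisms,
                                   models = models)),
      error = function(e) NULL)
    if (is.null(json)) return(err(400L, "could not ground input"))
    return(list(status = 200L, body = json))
  }
  err(404L, paste0("no such endpoint: ", method, " ", path))
}

#' Serve the grounding REST service
#'
#' Minimal blocking HTTP/1.1 loop over a base-R server socket, one request
#' per connection, dispatching to [handle_request()].  Suitable for local
#' use and testing; it is single-threaded by design.
#'
#' @param index A `grounding_index`.
#' @param models Optional disambiguator registry.
#' @param host,port Bind address.
#' @param max_requests Stop after this many requests (default unlimited).
#' @return The number of requests served, invisibly.
#' @export
serve <- function(index, models = NULL, host = "127.0.0.1", port = 8084,
                  max_requests = Inf) {
  served <- 0
  while (served < max_requests) {
    con <- suppressWarnings(socketConnection(
      host = host, port = port, server = TRUE, blocking = TRUE,
      open = "r+b", timeout = 30))
    res <- tryCatch({
      req <- read_http_request(con)
      if (is.null(req)) {
        list(status = 400L, body = '{"error":"malformed request"}')
      } else {
        handle_request(req$method, req$path, req$body, index, models)
      }
    }, error = function(e) {
      list(status = 500L, body = as.character(
        jsonlite::toJSON(list(error = conditionMessage(e)), auto_unbox = TRUE)))
    })
    payload <- charToRaw(res$body)
    status_text <- c(`200` = "OK", `400` = "Bad Request", `404` = "Not Found",
                     `413` = "Payload Too Large",
                     `500` = "Internal Server Error")[as.character(res$status)]
    header <- paste0("HTTP/1.1 ", res$status, " ",
                     status_text %||% "Error", "\r\n",
                     "Content-Type: application/json\r\n",
                     "Content-Length: ", length(payload), "\r\n",
                     "Connection: close\r\n\r\n")
    writeBin(c(charToRaw(header), payload), con)
    close(con)
    served <- served + 1
  }
  invisible(served)
}

read_http_request <- function(con) {
  request_line <- readLines(con, n = 1L)
  if (length(request_line) == 0) return(NULL)
  parts <- strsplit(trimws(request_line), " +")[[1]]
  if (length(parts) < 2L) return(NULL)
  content_length <- 0L
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0 || trimws(line) == "") break
    kv <- strsplit(line, ":", fixed = TRUE)[[1]]
    if (tolower(trimws(kv[1])) == "content-length") {
      content_length <- as.integer(trimws(paste(kv[-1], collapse = ":")))
    }
  }
  body <- if (content_length > 0) {
    rawToChar(readBin(con, "raw", n = content_length))
  } else ""
  list(method = parts[1], path = parts[2], body = body)
}
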
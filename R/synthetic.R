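# Synthetic gold-annotated corpora.
#
# The original datasets behind the method (a shared-task set of discharge
# summaries, a dummy-EHR narrative set, and de-identified pathology reports)
# are not public. This module generates annotated stand-ins that reproduce
# their statistical structure -- which tag types occur, how densely, and in
# which sentence contexts -- from handcrafted clinical sentence templates.
# Three style presets mirror the sources: `mednlp` (discharge-summary-like,
# age/sex/time/hospital, no person names), `dummy_ehr` (longer narrative,
# all five types, person rare), `pathology` (short reports dominated by
# person/hospital/time; age and sex absent).
#
# A configurable fraction of documents is "rule-conforming": every entity
# in them is realized in a form the rule-based tagger covers. The remaining
# documents mix in rule-breaking variants (kanji-numeral ages, clinic names
# without a suffix, bare 男/女, clinical inspection values in the xx/yy
# format that collide with slash dates) plus person names, which no rule
# covers. This contrast is what lets the learned taggers beat the rules.

synth_styles <- function() c("mednlp", "dummy_ehr", "pathology")

#' Entity-density presets per corpus style
#'
#' Expected spans per sentence per tag type for each style. The presets
#' keep the qualitative distribution of the emulated sources (pathology:
#' person/hospital/time only; discharge summaries: no person), with rates
#' boosted enough that every type present in a style appears at test-corpus
#' scale.
#'
#' @param style One of `"mednlp"`, `"dummy_ehr"`, `"pathology"`.
#' @return A tibble with columns `tag_type` and `density`.
#' @export
style_entity_density <- function(style = synth_styles()) {
  style <- match.arg(style)
  d <- switch(style,
    mednlp    = c(a = 0.18, x = 0.18, t = 0.52, h = 0.20, p = 0.00),
    dummy_ehr = c(a = 0.07, x = 0.07, t = 0.58, h = 0.15, p = 0.10),
    pathology = c(a = 0.00, x = 0.00, t = 0.20, h = 0.40, p = 0.45)
  )
  tibble::tibble(tag_type = names(d), density = unname(d))
}

#' Synthetic-corpus configuration
#'
#' @param n_documents Number of documents to generate.
#' @param style Corpus style preset (see [style_entity_density()]).
#' @param seed Integer seed; identical config + seed yields a byte-identical
#'   corpus.
#' @param conforming_fraction Fraction of documents restricted to
#'   rule-conforming entity realizations. Default per style: 0.8 (mednlp),
#'   0.7 (dummy_ehr), 0.25 (pathology; most pathology reports carry person
#'   names, which no rule covers).
#' @param sentences_per_doc Integer range (length-2) of sentences per
#'   document; style default 3-7 (mednlp), 8-16 (dummy_ehr), 2-4
#'   (pathology).
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(n_documents, style = synth_styles(), seed = 1,
                         conforming_fraction = NULL,
                         sentences_per_doc = NULL) {
  style <- match.arg(style)
  if (is.null(conforming_fraction)) {
    conforming_fraction <- switch(style, mednlp = 0.8, dummy_ehr = 0.7,
                                  pathology = 0.25)
  }
  if (is.null(sentences_per_doc)) {
    sentences_per_doc <- switch(style, mednlp = c(3L, 7L),
                                dummy_ehr = c(8L, 16L), pathology = c(2L, 4L))
  }
  stopifnot(n_documents >= 0, length(sentences_per_doc) == 2,
            conforming_fraction >= 0, conforming_fraction <= 1)
  structure(list(
    n_documents = as.integer(n_documents), style = style,
    seed = as.integer(seed), conforming_fraction = conforming_fraction,
    sentences_per_doc = as.integer(sentences_per_doc),
    entity_density = style_entity_density(style)
  ), class = "synth_config")
}

#' Generate surrogate name lists
#'
#' Emulates the external resources used for surrogate replacement: a large
#' list of hospital names (built as place/specialty stems plus one of the
#' suffixes 病院 / クリニック / 医院) and the 20 dummy family names and 20
#' dummy given names from which person surrogates are formed (a family name
#' alone, or family + given name).
#'
#' @param seed Integer seed.
#' @param n_hospitals Number of hospital names (>= 1).
#' @return A list of class `name_lists` with `hospital_names`,
#'   `family_names`, `given_names`.
#' @export
make_name_lists <- function(seed = 1, n_hospitals = 150) {
  stopifnot(n_hospitals >= 1)
  stems <- c("青葉", "中央", "大和", "港南", "山手",
             "旭", "若葉", "桜井", "藤沢", "富士見",
             "星川", "平和", "白石", "栄", "泉",
             "東", "西", "南", "北", "緑",
             "サクラ", "ヒカリ", "コスモ", "静大", "協立",
             "高砂", "川口", "相原", "久保", "宮前")
  specialties <- c("", "内科", "外科", "皮フ科", "眼科",
                   "小児科", "整形外科", "産婦人科",
                   "耳鼻咽喉科", "泌尿器科", "脳神経外科")
  suffixes <- default_rule_lexicon()$hospital_suffixes
  grid <- expand.grid(stem = stems, spec = specialties, suf = suffixes,
                      stringsAsFactors = FALSE)
  names_all <- paste0(grid$stem, grid$spec, grid$suf)
  hospitals <- with_seed(seed, {
    sample(names_all, min(n_hospitals, length(names_all)))
  })
  structure(list(
    hospital_names = hospitals,
    family_names = c("桑田", "佐藤", "鈴木", "高橋",
                     "伊藤", "渡辺", "山本", "中村",
                     "小林", "加藤", "吉田", "山田",
                     "松本", "井上", "木村", "斎藤",
                     "清水", "森田", "橋本", "石井"),
    given_names = c("智", "太郎", "花子", "健一",
                    "直樹", "恵子", "大輔", "由美",
                    "翔太", "美咲", "修平", "結衣",
                    "拓也", "真理", "和彦", "典子",
                    "隆", "幸子", "勇人", "明美")
  ), class = "name_lists")
}

# ---- entity realizations -------------------------------------------------

seg <- function(text, tag = NA_character_) list(text = text, tag = tag)

pick <- function(x) x[[sample.int(length(x), 1)]]

make_age_segment <- function(conforming) {
  if (!conforming && stats::runif(1) < 0.5) {
    # kanji-numeral ages: annotated gold, invisible to the numeral rule
    return(seg(pick(c("六十五歳", "七十歳", "八十六歳",
                      "九十二歳")), "a"))
  }
  if (stats::runif(1) < 0.15) {
    seg(paste0(sample(2:9, 1) * 10, "代"), "a")            # e.g. 60代
  } else {
    seg(paste0(sample(18:97, 1), pick(c("歳", "歳", "歳", "才"))), "a")
  }
}

make_sex_segment <- function(conforming) {
  if (!conforming && stats::runif(1) < 0.4) {
    return(seg(pick(c("男", "女")), "x"))        # bare 男 / 女
  }
  seg(pick(c("男性", "女性")), "x")
}

make_time_segment <- function(conforming, lexicon = default_rule_lexicon()) {
  if (!conforming && stats::runif(1) < 0.4) {
    return(seg(pick(c("深夜", "数日後", "三月")), "t"))
  }
  kind <- sample.int(4, 1)
  if (kind == 1) {                         # standalone calendar keyword
    kw <- pick(c("昨日", "本日", "今年", "先週",
                 "翌日", "同日", "先月", "今週", "来週", "前日"))
    ext <- if (stats::runif(1) < 0.4) pick(c("より", "から", "まで")) else ""
    seg(paste0(kw, ext), "t")
  } else if (kind == 2) {                  # numeral + classifier unit
    unit <- pick(c("年", "月", "週間", "日", "時", "分"))
    n <- switch(unit,
                "年" = sample(1:30, 1), "月" = sample(1:12, 1),
                "週間" = sample(1:8, 1), "日" = sample(1:31, 1),
                "時" = sample(0:23, 1), "分" = sample(1:59, 1))
    ext <- if (stats::runif(1) < 0.4) {
      pick(c("頃", "頃から", "から", "より", "まで", "ごろ"))
    } else ""
    seg(paste0(n, unit, ext), "t")
  } else if (kind == 3) {                  # yyyy/mm
    seg(sprintf("%d/%02d", sample(1990:2025, 1), sample(1:12, 1)), "t")
  } else {                                 # mm/dd
    seg(sprintf("%d/%d", sample(1:12, 1), sample(1:31, 1)), "t")
  }
}

make_hospital_segment <- function(conforming, lists) {
  if (!conforming && stats::runif(1) < 0.5) {
    stem <- strip_hospital_suffix(pick(lists$hospital_names))
    return(seg(stem, "h"))                 # clinic name without suffix
  }
  if (stats::runif(1) < 0.3) {
    seg(pick(c("当院", "近医", "同院")), "h")
  } else {
    seg(pick(lists$hospital_names), "h")
  }
}

strip_hospital_suffix <- function(name,
                                  suffixes = default_rule_lexicon()$hospital_suffixes) {
  for (sf in suffixes) {
    if (endsWith(name, sf)) {
      return(substr(name, 1, nchar(name) - nchar(sf)))
    }
  }
  name
}

make_person_segment <- function(lists) {
  fam <- pick(lists$family_names)
  if (stats::runif(1) < 0.5) {
    seg(fam, "p")
  } else {
    seg(paste(fam, pick(lists$given_names)), "p")
  }
}

# ---- sentence templates --------------------------------------------------

filler_ehr <- function() {
  pick(c("全身状態は良好である。",
         "特記すべき所見はない。",
         "既往に糖尿病がある。",
         "診断は肺炎とされた。",
         "内服を継続する。",
         "食欲は保たれている。",
         "経過は安定している。",
         "自覚症状は改善した。"))
}

filler_pathology <- function() {
  pick(c("悪性所見を認めない。",
         "組織学的に炎症像を認める。",
         "標本の状態は良好である。",
         "追加切片を作製した。"))
}

# categories -> probability, per style and conformity
sentence_weights <- function(style, conforming) {
  if (style == "pathology") {
    if (conforming) {
      c(hosp_only = 0.35, time_recv = 0.35, filler = 0.30)
    } else {
      c(hosp_person = 0.30, person_only = 0.15, hosp_only = 0.10,
        time_recv = 0.20, inspection = 0.10, filler = 0.15)
    }
  } else {
    base <- if (style == "mednlp") {
      c(age_sex = 0.18, time_symptom = 0.28, time_hosp = 0.12,
        hosp_only = 0.08, time_only = 0.12, filler = 0.22)
    } else {
      c(age_sex = 0.07, time_symptom = 0.30, time_hosp = 0.10,
        hosp_only = 0.05, person_sent = 0.10, time_only = 0.18,
        filler = 0.20)
    }
    if (conforming) {
      base <- base[setdiff(names(base), "person_sent")]
      base / sum(base)
    } else {
      c(base[setdiff(names(base), "filler")],
        inspection = 0.08, filler = unname(base["filler"]) - 0.08)
    }
  }
}

make_sentence <- function(style, conforming, lists) {
  w <- sentence_weights(style, conforming)
  cat_ <- sample(names(w), 1, prob = w)
  segs <- switch(cat_,
    age_sex = {
      intro <- pick(c("工場に勤めている",
                      "施設入所中で寝たきりの",
                      "独居の", "既往のない", ""))
      joiner <- pick(c("の", ""))
      list(seg(intro), make_age_segment(conforming), seg(joiner),
           make_sex_segment(conforming), seg("。"))
    },
    time_symptom = {
      tm <- make_time_segment(conforming)
      joiner <- if (grepl("(より|から|まで)$", tm$text)) "" else
        pick(c("に", "、"))
      symptom <- pick(c("発熱", "咳嗽", "腹痛", "頭痛",
                        "嘔気", "倦怠感", "胸痛"))
      tail <- pick(c("が出現した。", "を認めた。",
                     "が持続している。"))
      list(tm, seg(joiner), seg(symptom), seg(tail))
    },
    time_hosp = {
      tm <- make_time_segment(conforming)
      joiner <- if (grepl("(より|から|まで)$", tm$text)) "" else "に"
      list(tm, seg(joiner), make_hospital_segment(conforming, lists),
           seg(pick(c("を受診した。", "へ紹介された。"))))
    },
    hosp_only = {
      if (style == "pathology") {
        pick(list(
          list(seg("院外標本 "),
               make_hospital_segment(conforming, lists), seg("。")),
          list(make_hospital_segment(conforming, lists),
               seg("より提出された。"))
        ))
      } else {
        list(seg(pick(c("精査のため", "加療目的で", ""))),
             make_hospital_segment(conforming, lists),
             seg(pick(c("を受診した。", "に入院した。",
                        "へ通院中である。"))))
      }
    },
    time_only = {
      list(seg(pick(c("退院は", "次回診察は"))),
           make_time_segment(conforming),
           seg("の予定である。"))
    },
    person_sent = {
      list(seg(pick(c("担当医は", "家族の"))),
           make_person_segment(lists),
           seg(pick(c("とした。", "に説明した。"))))
    },
    hosp_person = {
      list(seg("院外標本 "), make_hospital_segment(conforming, lists),
           seg("、"), make_person_segment(lists), seg("。"))
    },
    person_only = {
      list(seg(pick(c("依頼医 ", "担当 "))),
           make_person_segment(lists), seg("。"))
    },
    time_recv = {
      tm <- make_time_segment(conforming)
      # a particle keeps kanji-final time expressions from fusing with the
      # following kanji verb during tokenization
      joiner <- if (grepl("(より|から|まで)$", tm$text)) "" else "に"
      list(tm, seg(joiner), seg(pick(c("受領した。", "提出された。"))))
    },
    inspection = {
      if (stats::runif(1) < 0.5) {
        # invalid month/day ranges: never a date
        list(seg(sprintf("検査値は%d/%dであった。",
                         sample(13:99, 1), sample(32:99, 1))))
      } else {
        # valid-looking xx/yy inspection value: collides with the date rule
        list(seg(sprintf("尿所見%d/%dを認めた。",
                         sample(1:12, 1), sample(1:31, 1))))
      }
    },
    filler = {
      list(seg(if (style == "pathology") filler_pathology() else filler_ehr()))
    }
  )
  assemble_segments(segs)
}

assemble_segments <- function(segs) {
  text <- ""
  spans <- list()
  for (s in segs) {
    if (!nzchar(s$text)) next
    b <- nchar_cp(text)
    text <- paste0(text, s$text)
    if (!is.na(s$tag)) {
      spans[[length(spans) + 1]] <- tibble::tibble(
        tag_type = s$tag, begin = b, end = b + nchar_cp(s$text))
    }
  }
  list(text = text,
       spans = if (length(spans)) dplyr::bind_rows(spans) else empty_spans())
}

#' Generate a synthetic annotated corpus
#'
#' Every inserted entity carries a gold span; spans never overlap and stay
#' within bounds. Identical config + seed yields a byte-identical corpus.
#'
#' @param config A [synth_config()].
#' @param lists Surrogate [make_name_lists()]; defaults to lists derived
#'   from the config seed.
#' @return A corpus tibble with the extra logical column `conforming`.
#' @export
#' @examples
#' corp <- generate_corpus(synth_config(3, "pathology", seed = 7))
#' corp$spans[[1]]
generate_corpus <- function(config, lists = NULL) {
  stopifnot(inherits(config, "synth_config"))
  if (is.null(lists)) lists <- make_name_lists(config$seed)
  n <- config$n_documents
  if (n == 0) {
    return(new_corpus(character(), character(), character(), list(),
                      extra = tibble::tibble(conforming = logical())))
  }
  with_seed(config$seed, {
    docs <- lapply(seq_len(n), function(i) {
      conforming <- stats::runif(1) < config$conforming_fraction
      n_sent <- sample(config$sentences_per_doc[1]:config$sentences_per_doc[2], 1)
      sep <- if (config$style == "pathology") "\n" else ""
      text <- ""
      spans <- list()
      for (s in seq_len(n_sent)) {
        sent <- make_sentence(config$style, conforming, lists)
        if (nzchar(text)) text <- paste0(text, sep)
        off <- nchar_cp(text)
        text <- paste0(text, sent$text)
        if (nrow(sent$spans)) {
          sh <- sent$spans
          sh$begin <- sh$begin + off
          sh$end <- sh$end + off
          spans[[length(spans) + 1]] <- sh
        }
      }
      spans <- if (length(spans)) dplyr::bind_rows(spans) else empty_spans()
      spans$begin <- as.integer(spans$begin)
      spans$end <- as.integer(spans$end)
      validate_spans(spans, nchar_cp(text), check_overlap = TRUE)
      new_corpus(sprintf("%s_%04d", config$style, i), text, config$style,
                 list(spans), extra = tibble::tibble(conforming = conforming))
    })
    dplyr::bind_rows(docs)
  })
}

#' Replace masking placeholders with surrogate names
#'
#' Pathology reports arrive with person and hospital names manually masked
#' as runs of ●, ◯, ▲ or ■. Each maximal placeholder run is replaced by a
#' randomly assigned surrogate name so that learned taggers can train on
#' natural-looking text. The run's target type must either be given by a
#' gold span covering it, or be inferable from an immediately following
#' hospital suffix; otherwise an error lists the offset. Span offsets are
#' recomputed; the affected gold span covers the full replacement name
#' (including a following suffix for hospital runs).
#'
#' @param corpus Corpus tibble whose texts may contain placeholder runs.
#' @param lists [make_name_lists()] to sample surrogates from.
#' @param seed Integer seed; replacement is deterministic per seed.
#' @return The corpus with placeholders replaced and spans updated.
#' @export
surrogate_replace <- function(corpus, lists = make_name_lists(1), seed = 1) {
  with_seed(seed, {
    for (i in seq_len(nrow(corpus))) {
      upd <- surrogate_replace_one(corpus$text[i], corpus$spans[[i]], lists)
      corpus$text[i] <- upd$text
      corpus$spans[[i]] <- upd$spans
    }
    corpus
  })
}

surrogate_replace_one <- function(text, spans, lists) {
  suffixes <- default_rule_lexicon()$hospital_suffixes
  repeat {
    m <- regexpr("[●◯▲■]+", text, perl = TRUE)
    if (m == -1) break
    b <- as.integer(m) - 1L                  # 0-based begin of run
    len <- attr(m, "match.length")
    e <- b + len
    covering <- which(spans$begin <= b & spans$end >= e)
    after <- substr_cp(text, e, min(nchar_cp(text), e + 8L))
    suf_hit <- suffixes[vapply(suffixes, function(sf) startsWith(after, sf),
                               logical(1))]
    type <- if (length(covering) && spans$tag_type[covering[1]] %in% c("h", "p")) {
      spans$tag_type[covering[1]]
    } else if (length(suf_hit)) {
      "h"
    } else {
      rlang::abort(sprintf(
        "placeholder run at offset %d has no determinable type", b))
    }
    repl <- if (type == "p") {
      fam <- pick(lists$family_names)
      if (stats::runif(1) < 0.5) fam else paste(fam, pick(lists$given_names))
    } else if (length(suf_hit)) {
      strip_hospital_suffix(pick(lists$hospital_names))   # suffix follows
    } else {
      pick(lists$hospital_names)
    }
    delta <- nchar_cp(repl) - len
    text <- paste0(substr_cp(text, 0, b), repl,
                   substr_cp(text, e, nchar_cp(text)))
    if (length(covering)) {
      spans$end[covering[1]] <- spans$end[covering[1]] + delta
    } else {
      # inferred hospital: new gold span over name + suffix
      spans <- dplyr::bind_rows(spans, tibble::tibble(
        tag_type = "h", begin = b,
        end = e + delta + nchar_cp(suf_hit[which.max(nchar_cp(suf_hit))])))
    }
    # spans lying entirely after the run shift by delta; the covering (or
    # newly created) span, whose begin is before the run end, already moved
    after_run <- spans$begin >= e
    spans$begin[after_run] <- spans$begin[after_run] + delta
    spans$end[after_run] <- spans$end[after_run] + delta
    spans <- dplyr::arrange(spans, .data$begin)
  }
  spans$begin <- as.integer(spans$begin)
  spans$end <- as.integer(spans$end)
  validate_spans(spans, nchar_cp(text), check_overlap = TRUE)
  list(text = text, spans = spans)
}
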
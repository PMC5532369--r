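#include <Rcpp.h>
#include <cstring>
using namespace Rcpp;

// Exhaustive three-letter placement of converted reads against the two
// converted reference strands. Reads and references must already be
// C->T converted; for circular references the caller passes strands
// extended by (max read length - 1) wrap bases and ref_len is the
// unextended length. Returns, per read, the best placement with at most
// max_mm mismatches plus the number of co-optimal placements (for
// ambiguity filtering).
// [[Rcpp::export]]
List cpp_align_reads(CharacterVector reads, std::string top,
                     std::string bot, int max_mm, int ref_len,
                     bool circular) {
  int n = reads.size();
  IntegerVector strand(n), start(n), mism(n), nbest(n);
  const char* refs[2] = {top.c_str(), bot.c_str()};
  int reflens[2] = {(int) top.size(), (int) bot.size()};

  for (int r = 0; r < n; ++r) {
    const char* rd = CHAR(STRING_ELT(reads, r));
    int len = (int) std::strlen(rd);
    int best = max_mm + 1, bs = 0, bp = 0, nb = 0;
    for (int s = 0; s < 2; ++s) {
      const char* rf = refs[s];
      int maxs = circular ? ref_len : reflens[s] - len + 1;
      for (int p = 0; p < maxs; ++p) {
        int mm = 0;
        bool worse = false;
        for (int i = 0; i < len; ++i) {
          if (rf[p + i] != rd[i]) {
            if (++mm > best || mm > max_mm) { worse = true; break; }
          }
        }
        if (worse) continue;
        if (mm < best) {
          best = mm; bs = s + 1; bp = p + 1; nb = 1;
        } else if (mm == best) {
          ++nb;
        }
      }
    }
    if (nb == 0) {
      strand[r] = 0; start[r] = NA_INTEGER; mism[r] = NA_INTEGER;
    } else {
      strand[r] = bs; start[r] = bp; mism[r] = best;
    }
    nbest[r] = nb;
  }
  return List::create(_["strand"] = strand, _["start"] = start,
                      _["mismatches"] = mism, _["n_best"] = nbest);
}

// Accumulate methylation calls at reference cytosines from placed reads.
// strand: 1 = top, 2 = bottom (0/NA skipped); start: 1-based in the
// strand's own coordinates. top/bot are the ORIGINAL (unconverted)
// strand sequences, extended by wrap bases for circular references.
// Returns per-strand methylated / unmethylated call counts indexed by
// the strand's own 1..ref_len coordinates.
// [[Rcpp::export]]
List cpp_count_calls(CharacterVector reads, IntegerVector strand,
                     IntegerVector start, std::string top,
                     std::string bot, int ref_len, bool circular) {
  int n = reads.size();
  IntegerVector meth_top(ref_len), unmeth_top(ref_len);
  IntegerVector meth_bot(ref_len), unmeth_bot(ref_len);
  const char* refs[2] = {top.c_str(), bot.c_str()};

  for (int r = 0; r < n; ++r) {
    if (strand[r] == NA_INTEGER || strand[r] < 1) continue;
    int s = strand[r] - 1;
    const char* rf = refs[s];
    const char* rd = CHAR(STRING_ELT(reads, r));
    int len = (int) std::strlen(rd);
    int p0 = start[r] - 1;
    for (int i = 0; i < len; ++i) {
      if (rf[p0 + i] != 'C') continue;
      int pos = circular ? (p0 + i) % ref_len : p0 + i;
      char c = rd[i];
      if (c == 'C') {
        if (s == 0) ++meth_top[pos]; else ++meth_bot[pos];
      } else if (c == 'T') {
        if (s == 0) ++unmeth_top[pos]; else ++unmeth_bot[pos];
      }
    }
  }
  return List::create(_["meth_top"] = meth_top,
                      _["unmeth_top"] = unmeth_top,
                      _["meth_bot"] = meth_bot,
                      _["unmeth_bot"] = unmeth_bot);
}
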
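#include <Rcpp.h>
#include "fq_archive.h"

using namespace Rcpp;

static std::vector<std::string> toStd(const CharacterVector& x) {
  std::vector<std::string> v;
  v.reserve(x.size());
  for (R_xlen_t i = 0; i < x.size(); ++i) v.push_back(as<std::string>(x[i]));
  return v;
}

static CharacterVector toR(const std::vector<std::string>& v) {
  CharacterVector x(v.size());
  for (size_t i = 0; i < v.size(); ++i) x[i] = v[i];
  return x;
}

static CharacterVector hexDigests(const std::vector<uint64_t>& d) {
  CharacterVector out(d.size());
  char buf[17];
  for (size_t i = 0; i < d.size(); ++i) {
    snprintf(buf, sizeof(buf), "%016llx",
             static_cast<unsigned long long>(d[i]));
    out[i] = buf;
  }
  return out;
}

// [[Rcpp::export]]
List cppCompress(CharacterVector id1, CharacterVector seq1,
                 CharacterVector qual1, CharacterVector id2,
                 CharacterVector seq2, CharacterVector qual2, bool paired,
                 bool reo, int qualMode, int idMode, double genomeSize,
                 double blockSize, IntegerVector tierSizes,
                 IntegerVector qualSym, IntegerVector qualRep) {
  fq::Params P;
  P.paired = paired;
  P.reo = reo;
  P.qualMode = qualMode;
  P.idMode = idMode;
  P.genomeSize = static_cast<uint64_t>(genomeSize);
  P.blockSize = static_cast<uint64_t>(blockSize);
  P.e = tierSizes[0]; P.p = tierSizes[1];
  P.s = tierSizes[2]; P.b = tierSizes[3];
  if (qualMode != fq::QMODE_NONE) {
    if (qualSym.size() != fq::QRANGE) stop("quality symbol table must have 94 entries");
    P.qualSym.assign(qualSym.begin(), qualSym.end());
    P.qualRep.assign(qualRep.begin(), qualRep.end());
  }
  std::vector<std::string> i1 = toStd(id1), s1 = toStd(seq1), q1 = toStd(qual1);
  std::vector<std::string> i2, s2, q2;
  if (paired) { i2 = toStd(id2); s2 = toStd(seq2); q2 = toStd(qual2); }

  fq::CompressResult res;
  try {
    res = fq::compressRecords(P, i1, s1, q1, i2, s2, q2);
  } catch (const std::exception& e) {
    stop(e.what());
  }

  RawVector a(res.archive.size());
  std::copy(res.archive.begin(), res.archive.end(), a.begin());
  NumericVector sb = NumericVector::create(
      _["bases"] = static_cast<double>(res.streamBytes[fq::ST_BASES]),
      _["lengths"] = static_cast<double>(res.streamBytes[fq::ST_LEN]),
      _["ids"] = static_cast<double>(res.streamBytes[fq::ST_IDS]),
      _["qualities"] = static_cast<double>(res.streamBytes[fq::ST_QUAL]),
      _["pe"] = static_cast<double>(res.streamBytes[fq::ST_PE]),
      _["prefix"] = static_cast<double>(res.streamBytes[fq::ST_PREF]));
  return List::create(
      _["archive"] = a, _["digests"] = hexDigests(res.digests),
      _["streamBytes"] = sb,
      _["nBases"] = static_cast<double>(res.nBases),
      _["nBlocks"] = static_cast<double>(res.nBlocks),
      _["peHit"] = static_cast<double>(res.peHit),
      _["peMiss"] = static_cast<double>(res.peMiss),
      _["nCorrections"] = static_cast<double>(res.nCorrections));
}

// [[Rcpp::export]]
List cppDecompress(RawVector archive) {
  fq::DecompressResult res;
  try {
    res = fq::decompressArchive(
        reinterpret_cast<const uint8_t*>(RAW(archive)), archive.size());
  } catch (const std::exception& e) {
    stop(e.what());
  }
  List out = List::create(
      _["id1"] = toR(res.id1), _["seq1"] = toR(res.seq1),
      _["qual1"] = toR(res.qual1), _["paired"] = res.paired,
      _["digests"] = hexDigests(res.digests));
  if (res.paired) {
    out["id2"] = toR(res.id2);
    out["seq2"] = toR(res.seq2);
    out["qual2"] = toR(res.qual2);
  }
  return out;
}

// [[Rcpp::export]]
List cppArchiveInfo(RawVector archive) {
  try {
    fq::ArchiveHeader H = fq::readHeader(
        reinterpret_cast<const uint8_t*>(RAW(archive)), archive.size());
    NumericVector bu(H.blkUnits.size());
    NumericMatrix bl(H.blkUnits.size(), fq::N_STREAMS);
    for (size_t i = 0; i < H.blkUnits.size(); ++i) {
      bu[i] = H.blkUnits[i];
      for (int st = 0; st < fq::N_STREAMS; ++st) bl(i, st) = H.blkLens[i][st];
    }
    colnames(bl) = CharacterVector::create("bases", "lengths", "ids",
                                           "qualities", "pe", "prefix");
    IntegerVector qr(H.P.qualRep.begin(), H.P.qualRep.end());
    return List::create(
        _["paired"] = H.P.paired, _["reo"] = H.P.reo,
        _["qualMode"] = H.P.qualMode, _["idMode"] = H.P.idMode,
        _["genomeSize"] = static_cast<double>(H.P.genomeSize),
        _["blockSize"] = static_cast<double>(H.P.blockSize),
        _["tierSizes"] = IntegerVector::create(_["e"] = H.P.e, _["p"] = H.P.p,
                                               _["s"] = H.P.s, _["b"] = H.P.b),
        _["nUnits"] = static_cast<double>(H.nUnits),
        _["nBlocks"] = static_cast<double>(H.blkUnits.size()),
        _["blockUnits"] = bu, _["blockStreamBytes"] = bl,
        _["qualAlphabet"] = qr);
  } catch (const std::exception& e) {
    stop(e.what());
  }
}
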
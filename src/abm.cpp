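// Agent-based model core: binomial-thinning division/death updates with
// per-copy chromosome missegregation, serial passaging at capacity, and
// multinomial sampling. Uses R's RNG throughout so runs are reproducible
// from set.seed(); fitness is resolved through an R callback, batched over
// the karyotypes newly created since the previous call.
#include <Rcpp.h>
#include <unordered_map>
#include <string>
#include <vector>
#include <array>
using namespace Rcpp;

namespace {

const int NCHR = 22;

struct Population {
  std::vector<std::array<int, NCHR>> karyo;   // all karyotypes ever seen
  std::vector<double> counts;                 // current cell counts
  std::vector<double> fitness;                // per-karyotype fitness
  std::vector<char> fitKnown;
  std::unordered_map<std::string, int> index;

  std::string keyOf(const std::array<int, NCHR> &k) {
    std::string s(NCHR, '\0');
    for (int c = 0; c < NCHR; c++) s[c] = (char)(k[c] & 0xff);
    return s;
  }
  int add(const std::array<int, NCHR> &k) {
    std::string key = keyOf(k);
    auto it = index.find(key);
    if (it != index.end()) return it->second;
    int id = (int)karyo.size();
    karyo.push_back(k);
    counts.push_back(0.0);
    fitness.push_back(NA_REAL);
    fitKnown.push_back(0);
    index.emplace(std::move(key), id);
    return id;
  }
};

// resolve fitness for karyotypes with fitKnown == 0 via the R callback
void resolveFitness(Population &pop, Function fitnessFun) {
  std::vector<int> need;
  for (size_t i = 0; i < pop.karyo.size(); i++)
    if (!pop.fitKnown[i]) need.push_back((int)i);
  if (need.empty()) return;
  IntegerMatrix km((int)need.size(), NCHR);
  for (size_t r = 0; r < need.size(); r++)
    for (int c = 0; c < NCHR; c++) km(r, c) = pop.karyo[need[r]][c];
  NumericVector f = fitnessFun(km);
  for (size_t r = 0; r < need.size(); r++) {
    pop.fitness[need[r]] = f[r];
    pop.fitKnown[need[r]] = 1;
  }
}

// truncated Binomial(C, p) conditioned on >= 1, via inverse CDF
int truncBinomGe1(int C, double p, std::vector<double> &pmCache) {
  if ((int)pmCache.size() != C) {
    pmCache.resize(C);
    for (int m = 1; m <= C; m++) pmCache[m - 1] = R::dbinom(m, C, p, 0);
    double tot = 0;
    for (double v : pmCache) tot += v;
    for (double &v : pmCache) v /= tot;
  }
  double u = unif_rand(), acc = 0;
  for (int m = 1; m <= C; m++) {
    acc += pmCache[m - 1];
    if (u <= acc) return m;
  }
  return C;
}

// multinomial draw of n cells by sequential conditional binomials
std::vector<double> multinomDraw(const std::vector<double> &w, double n) {
  std::vector<double> out(w.size(), 0.0);
  double rem = 0;
  for (double v : w) rem += v;
  double left = n;
  for (size_t i = 0; i < w.size() && left > 0; i++) {
    if (w[i] <= 0) { rem -= w[i]; continue; }
    double take = (rem <= w[i]) ? left
      : R::rbinom(left, w[i] / rem);
    out[i] = take;
    left -= take;
    rem -= w[i];
  }
  return out;
}

} // namespace

// [[Rcpp::export(name = ".abm_run")]]
List abm_run(IntegerMatrix founderK, NumericVector founderN,
             Function fitnessFun, double p, double nMax, double nSeed,
             double dt, double tEnd, double sampleSize,
             NumericVector sampleTimes) {
  Population pop;
  for (int r = 0; r < founderK.nrow(); r++) {
    std::array<int, NCHR> k;
    for (int c = 0; c < NCHR; c++) k[c] = founderK(r, c);
    int id = pop.add(k);
    pop.counts[id] += founderN[r];
  }

  std::unordered_map<int, std::vector<double>> pmCaches;
  std::vector<double> sampT;
  std::vector<int> sampIdx;
  std::vector<double> sampCnt;
  std::vector<double> passageTimes;
  bool extinct = false;
  double t = 0;
  int nSteps = (int)std::ceil(tEnd / dt - 1e-9);
  size_t pendingSample = 0;
  NumericVector st = clone(sampleTimes).sort();

  double lastSampleTime = -1.0;
  auto recordSample = [&](double time) {
    lastSampleTime = time;
    std::vector<double> s = multinomDraw(pop.counts, sampleSize);
    for (size_t i = 0; i < s.size(); i++) {
      if (s[i] > 0) {
        sampT.push_back(time);
        sampIdx.push_back((int)i + 1);
        sampCnt.push_back(s[i]);
      }
    }
  };

  for (int step = 0; step < nSteps; step++) {
    resolveFitness(pop, fitnessFun);
    size_t nNow = pop.karyo.size();   // daughters append beyond this
    for (size_t i = 0; i < nNow; i++) {
      double cnt = pop.counts[i];
      if (cnt <= 0) continue;
      double f = pop.fitness[i];
      if (ISNAN(f)) { pop.counts[i] = 0; continue; }  // lethal (off-table)
      if (std::abs(f) * dt >= 1)
        stop("|fitness| * dt >= 1; use a smaller dt");
      if (f < 0) {
        pop.counts[i] = cnt - R::rbinom(cnt, -f * dt);
        continue;
      }
      double ndiv = R::rbinom(cnt, f * dt);
      if (ndiv <= 0) continue;
      if (p <= 0) { pop.counts[i] = cnt + ndiv; continue; }
      const std::array<int, NCHR> k = pop.karyo[i];
      int C = 0;
      for (int c = 0; c < NCHR; c++) C += k[c];
      double pClean = std::pow(1.0 - p, C);
      double nms = R::rbinom(ndiv, 1.0 - pClean);
      pop.counts[i] = cnt + ndiv - 2.0 * nms;
      if (nms <= 0) continue;
      std::vector<double> &pmC = pmCaches[C];
      for (int e = 0; e < (int)nms; e++) {
        int mTotal = truncBinomGe1(C, p, pmC);
        // allocate missegregating copies among chromosomes, uniformly
        // over the C physical copies without replacement
        int m[NCHR] = {0};
        int remTot = C;
        int rem[NCHR];
        for (int c = 0; c < NCHR; c++) rem[c] = k[c];
        for (int d = 0; d < mTotal; d++) {
          double u = unif_rand() * remTot;
          double acc = 0;
          for (int c = 0; c < NCHR; c++) {
            acc += rem[c];
            if (u <= acc) { m[c]++; rem[c]--; remTot--; break; }
          }
        }
        std::array<int, NCHR> d1, d2;
        bool ok1 = true, ok2 = true;
        for (int c = 0; c < NCHR; c++) {
          int g = (m[c] > 0) ? (int)R::rbinom(m[c], 0.5) : 0;
          int delta = 2 * g - m[c];
          d1[c] = k[c] + delta;
          d2[c] = k[c] - delta;
          if (d1[c] == 0) ok1 = false;
          if (d2[c] == 0) ok2 = false;
        }
        if (ok1) pop.counts[pop.add(d1)] += 1;
        if (ok2) pop.counts[pop.add(d2)] += 1;
      }
    }
    t = (step + 1) * dt;
    double total = 0;
    for (double v : pop.counts) total += v;
    if (total <= 0) { extinct = true; break; }
    while (pendingSample < (size_t)st.size() &&
           t >= st[pendingSample] - 1e-9) {
      recordSample(st[pendingSample]);
      pendingSample++;
    }
    if (total >= nMax) {
      // avoid a duplicate observation when a passage coincides with a
      // scheduled sampling time
      if (std::abs(t - lastSampleTime) > 1e-9) recordSample(t);
      passageTimes.push_back(t);
      pop.counts = multinomDraw(pop.counts, nSeed);
    }
  }

  IntegerMatrix km((int)pop.karyo.size(), NCHR);
  for (size_t r = 0; r < pop.karyo.size(); r++)
    for (int c = 0; c < NCHR; c++) km(r, c) = pop.karyo[r][c];
  return List::create(
    _["karyotypes"] = km,
    _["finalCounts"] = NumericVector(pop.counts.begin(), pop.counts.end()),
    _["t"] = t,
    _["sample_time"] = NumericVector(sampT.begin(), sampT.end()),
    _["sample_idx"] = IntegerVector(sampIdx.begin(), sampIdx.end()),
    _["sample_count"] = NumericVector(sampCnt.begin(), sampCnt.end()),
    _["passageTimes"] = NumericVector(passageTimes.begin(),
                                      passageTimes.end()),
    _["extinct"] = extinct);
}
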
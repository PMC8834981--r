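{"type":"FeatureCollection","features":[{"type":"Feature","properties":{},"geometry":{"type":"LineString","coordinates":[[1000,1000],[1000,1100]]}},{"type":"Feature","properties":{},"geometry":{"type":"LineString","coordinates":[[1000,1100],[1000,1200]]}},{"type":"Feature","properties":{},"geometry":{"type":"LineString","coordinates":[[1000,1200],[1000,1300]]}},{"type":"Feature","properties":{},"geometry":{"type":"LineString","coordinates":[[1000,1300],[1000,1400]]}},{"type":"Feature","properties":{},"geometry":{"type":"LineString","coordinates":[[1100,1000],[1100,1100]]}},{"type":"Feature","properties":{},"geometry":{"type":"LineString","coordinates":[[1100,1100],[1100,1200]]}},{"type":"Feature","properties":{},"geometry":{"type":"LineString","coordinates":[[1100,1200],[1100,1300]]}},{"type":"Feature","properties":{},"geometry":{"type":"LineString","coordinates":[[1100,1300],[1100,1400]]}},{"type":"Feature","properties":{},"geometry":{"type":"LineString","coordinates":[[1200,1000],[1200,1100]]}},{"type":"Feature","properties":{},"geometry":{"type":"LineString","coordinates":[[1200,1100],[1200,1200]]}},{"type":"Feature","properties":{},"geometry":{"type":"LineString","coordinates":[[1200,1200],[1200,1300]]}},{"type":"Feature","properties":{},"geometry":{"type":"LineString","coordinates":[[1200,1300],[1200,1400]]}},{"type":"Feature","properties":{},"geometry":{"type":"LineString","coordinates":[[1300,1000],[1300,1100]]}},{"type":"Feature","properties":{},"geometry":{"type":"LineString","coordinates":[[1300,1100],[1300,1200]]}},{"type":"Feature","properties":{},"geometry":{"type":"LineString","coordinates":[[1300,1200],[1300,1300]]}},{"type":"Feature","properties":{},"geometry":{"type":"LineString","coordinates":[[1300,1300],[1300,1400]]}},{"type":"Feature","properties":{},"geometry":{"type":"LineString","coordinates":[[1400,1000],[1400,1100]]}},{"type":"Feature","properties":{},"geometry":{"type":"LineString","coordinates":[[1400,1100],[1400,1200]]}},{"type":"Feature","properties":{},"geometry":{"type":"LineString","coordinates":[[1400,1200],[1400,1300]]}},{"type":"Feature","properties":{},"geometry":{"type":"LineString","coordinates":[[1400,1300],[1400,1400]]}},{"type":"Feature","properties":{},"geometry":{"type":"LineString","coordinates":[[1000,1000],[1100,1000]]}},{"type":"Feature","properties":{},"geometry":{"type":"LineString","coordinates":[[1100,1000],[1200,1000]]}},{"type":"Feature","properties":{},"geometry":{"type":"LineString","coordinates":[[1200,1000],[1300,1000]]}},{"type":"Feature","properties":{},"geometry":{"type":"LineString","coordinates":[[1300,1000],[1400,1000]]}},{"type":"Feature","properties":{},"geometry":{"type":"LineString","coordinates":[[1000,1100],[1100,1100]]}},{"type":"Feature","properties":{},"geometry":{"type":"LineString","coordinates":[[1100,1100],[1200,1100]]}},{"type":"Feature","properties":{},"geometry":{"type":"LineString","coordinates":[[1200,1100],[1300,1100]]}},{"type":"Feature","properties":{},"geometry":{"type":"LineString","coordinates":[[1300,1100],[1400,1100]]}},{"type":"Feature","properties":{},"geometry":{"type":"LineString","coordinates":[[1000,1200],[1100,1200]]}},{"type":"Feature","properties":{},"geometry":{"type":"LineString","coordinates":[[1100,1200],[1200,1200]]}},{"type":"Feature","properties":{},"geometry":{"type":"LineString","coordinates":[[1200,1200],[1300,1200]]}},{"type":"Feature","properties":{},"geometry":{"type":"LineString","coordinates":[[1300,1200],[1400,1200]]}},{"type":"Feature","properties":{},"geometry":{"type":"LineString","coordinates":[[1000,1300],[1100,1300]]}},{"type":"Feature","properties":{},"geometry":{"type":"LineString","coordinates":[[1100,1300],[1200,1300]]}},{"type":"Feature","properties":{},"geometry":{"type":"LineString","coordinates":[[1200,1300],[1300,1300]]}},{"type":"Feature","properties":{},"geometry":{"type":"LineString","coordinates":[[1300,1300],[1400,1300]]}},{"type":"Feature","properties":{},"geometry":{"type":"LineString","coordinates":[[1000,1400],[1100,1400]]}},{"type":"Feature","properties":{},"geometry":{"type":"LineString","coordinates":[[1100,1400],[1200,1400]]}},{"type":"Feature","properties":{},"geometry":{"type":"LineString","coordinates":[[1200,1400],[1300,1400]]}},{"type":"Feature","properties":{},"geometry":{"type":"LineString","coordinates":[[1300,1400],[1400,1400]]}}]}
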
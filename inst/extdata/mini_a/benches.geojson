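{"type":"FeatureCollection","features":[{"type":"Feature","properties":{"id":1,"kind":"formal","zone":"A"},"geometry":{"type":"Point","coordinates":[1400,1065.08341712179]}},{"type":"Feature","properties":{"id":2,"kind":"bus_stop","zone":"A"},"geometry":{"type":"Point","coordinates":[1400,1251.96613703156]}},{"type":"Feature","properties":{"id":3,"kind":"bus_stop","zone":"A"},"geometry":{"type":"Point","coordinates":[1000,1110.15343609033]}},{"type":"Feature","properties":{"id":4,"kind":"formal","zone":"A"},"geometry":{"type":"Point","coordinates":[1067.87663110299,1400]}},{"type":"Feature","properties":{"id":5,"kind":"informal","zone":"A"},"geometry":{"type":"Point","coordinates":[1378.37857156992,1000]}},{"type":"Feature","properties":{"id":6,"kind":"bus_stop","zone":"A"},"geometry":{"type":"Point","coordinates":[1101.97533054743,1300]}},{"type":"Feature","properties":{"id":7,"kind":"bus_stop","zone":"A"},"geometry":{"type":"Point","coordinates":[1077.80554767232,1400]}},{"type":"Feature","properties":{"id":8,"kind":"formal","zone":"A"},"geometry":{"type":"Point","coordinates":[1103.6208631238,1400]}}]}
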
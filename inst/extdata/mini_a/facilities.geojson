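{"type":"FeatureCollection","features":[{"type":"Feature","properties":{"id":1,"group":"health_services","subtype":"health_services","zone":"A"},"geometry":{"type":"Point","coordinates":[1400,1085.00529652229]}},{"type":"Feature","properties":{"id":2,"group":"municipal","subtype":"municipal","zone":"A"},"geometry":{"type":"Point","coordinates":[1150,1384.27904031705]}},{"type":"Feature","properties":{"id":3,"group":"shopping","subtype":"shopping","zone":"A"},"geometry":{"type":"Point","coordinates":[1382.13011797052,1000]}},{"type":"Feature","properties":{"id":4,"group":"shopping","subtype":"shopping","zone":"A"},"geometry":{"type":"Point","coordinates":[1000,1041.99592814548]}},{"type":"Feature","properties":{"id":5,"group":"shopping","subtype":"shopping","zone":"A"},"geometry":{"type":"Point","coordinates":[1304.73011373542,1000]}}]}
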
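{"type":"FeatureCollection","features":[{"type":"Feature","properties":{"id":1,"kind":"formal","zone":"B"},"geometry":{"type":"Point","coordinates":[1335.98717767745,1000]}},{"type":"Feature","properties":{"id":2,"kind":"formal","zone":"B"},"geometry":{"type":"Point","coordinates":[1010.21334074903,1000]}},{"type":"Feature","properties":{"id":3,"kind":"formal","zone":"B"},"geometry":{"type":"Point","coordinates":[1040.0484405458,1300]}},{"type":"Feature","properties":{"id":4,"kind":"formal","zone":"B"},"geometry":{"type":"Point","coordinates":[1240.98930321634,1000]}},{"type":"Feature","properties":{"id":5,"kind":"formal","zone":"B"},"geometry":{"type":"Point","coordinates":[1100,1044.48443939909]}},{"type":"Feature","properties":{"id":6,"kind":"formal","zone":"B"},"geometry":{"type":"Point","coordinates":[1400,1139.72435805481]}},{"type":"Feature","properties":{"id":7,"kind":"bus_stop","zone":"B"},"geometry":{"type":"Point","coordinates":[1000,1090.04245821852]}},{"type":"Feature","properties":{"id":8,"kind":"formal","zone":"B"},"geometry":{"type":"Point","coordinates":[1300,1205.77271650545]}},{"type":"Feature","properties":{"id":9,"kind":"informal","zone":"B"},"geometry":{"type":"Point","coordinates":[1083.1601977814,1400]}},{"type":"Feature","properties":{"id":10,"kind":"informal","zone":"B"},"geometry":{"type":"Point","coordinates":[1400,1196.03210892528]}},{"type":"Feature","properties":{"id":11,"kind":"informal","zone":"B"},"geometry":{"type":"Point","coordinates":[1026.88404533546,1400]}},{"type":"Feature","properties":{"id":12,"kind":"formal","zone":"B"},"geometry":{"type":"Point","coordinates":[1304.66431754176,1100]}},{"type":"Feature","properties":{"id":13,"kind":"formal","zone":"B"},"geometry":{"type":"Point","coordinates":[1185.39425709751,1300]}},{"type":"Feature","properties":{"id":14,"kind":"formal","zone":"B"},"geometry":{"type":"Point","coordinates":[1400,1270.23406757507]}},{"type":"Feature","properties":{"id":15,"kind":"formal","zone":"B"},"geometry":{"type":"Point","coordinates":[1138.81668755785,1100]}},{"type":"Feature","properties":{"id":16,"kind":"bus_stop","zone":"B"},"geometry":{"type":"Point","coordinates":[1177.41525992751,1400]}},{"type":"Feature","properties":{"id":17,"kind":"formal","zone":"B"},"geometry":{"type":"Point","coordinates":[1163.70833492838,1200]}},{"type":"Feature","properties":{"id":18,"kind":"formal","zone":"B"},"geometry":{"type":"Point","coordinates":[1300,1341.67257917579]}},{"type":"Feature","properties":{"id":19,"kind":"bus_stop","zone":"B"},"geometry":{"type":"Point","coordinates":[1337.51048336271,1400]}},{"type":"Feature","properties":{"id":20,"kind":"formal","zone":"B"},"geometry":{"type":"Point","coordinates":[1209.35500941705,1300]}},{"type":"Feature","properties":{"id":21,"kind":"informal","zone":"B"},"geometry":{"type":"Point","coordinates":[1237.55409971345,1400]}},{"type":"Feature","properties":{"id":22,"kind":"formal","zone":"B"},"geometry":{"type":"Point","coordinates":[1116.32000750396,1100]}},{"type":"Feature","properties":{"id":23,"kind":"informal","zone":"B"},"geometry":{"type":"Point","coordinates":[1248.10022576712,1000]}},{"type":"Feature","properties":{"id":24,"kind":"formal","zone":"B"},"geometry":{"type":"Point","coordinates":[1136.05984479655,1100]}},{"type":"Feature","properties":{"id":25,"kind":"formal","zone":"B"},"geometry":{"type":"Point","coordinates":[1200,1379.23738011159]}}]}
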
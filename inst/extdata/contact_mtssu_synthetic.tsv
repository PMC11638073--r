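	bS1m	bS6m	bS16m	bS18m	bS21m	uS2m	uS3m	uS5m	uS7m	uS9m	uS10m	uS11m	uS12m	uS14m	uS15m	uS17m	mS22	mS23	mS25	mS26	mS27	mS29	mS31	mS33	mS34	mS35	mS37	mS38	mS39	mS40
bS1m	0	847.2	0	0	0	281.5	0	0	0	434.7	0	0	0	0	0	0	0	777.9	0	0	0	0	0	0	0	0	0	0	0	0
bS6m	847.2	0	0	0	0	789.6	0	0	0	0	0	0	0	0	0	0	0	1244	0	0	0	0	0	0	0	0	0	0	0	0
bS16m	0	0	0	0	0	0	0	0	0	709.3	0	0	0	0	0	0	0	0	0	0	1064.4	0	0	0	471.8	0	0	0	0	1342.5
bS18m	0	0	0	0	0	0	0	586.2	0	0	0	0	0	0	0	0	0	934.4	0	0	0	0	0	0	0	0	0	0	0	0
bS21m	0	0	0	0	0	0	0	0	0	0	0	345.9	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0
uS2m	281.5	789.6	0	0	0	0	0	0	0	962.9	0	0	0	0	0	0	0	1241.5	0	0	0	0	0	0	0	1296.7	0	0	0	0
uS3m	0	0	0	0	0	0	0	0	527.4	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0
uS5m	0	0	0	586.2	0	0	0	0	0	0	0	0	0	0	0	0	0	262.4	0	0	0	0	0	0	0	0	0	0	0	0
uS7m	0	0	0	0	0	0	527.4	0	0	0	379.3	785.5	896.2	0	925.4	0	0	0	0	0	0	0	0	0	0	0	625	0	0	0
uS9m	434.7	0	709.3	0	0	962.9	0	0	0	0	1032.6	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0
uS10m	0	0	0	0	0	0	0	0	379.3	1032.6	0	0	0	0	0	0	0	0	0	0	0	0	0	661.8	0	865	0	0	0	1291
uS11m	0	0	0	0	345.9	0	0	0	785.5	0	0	0	342.3	0	0	0	0	0	0	0	0	0	0	0	0	0	1369.6	0	0	0
uS12m	0	0	0	0	0	0	0	0	896.2	0	0	342.3	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0
uS14m	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	1369.7	1012.3	0	0	0	0	0	0	0
uS15m	0	0	0	0	0	0	0	0	925.4	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	979.3	0
uS17m	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	1165	1217	0	0	0	0	0	0	0	0	0	588.6
mS22	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	782.1	0	0	0	0	0	735.5	0	0	0	0	761.9
mS23	777.9	1244	0	934.4	0	1241.5	0	262.4	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0
mS25	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	1165	782.1	0	0	0	0	0	0	0	0	0	0	0	0	0
mS26	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	1217	0	0	0	0	1395.4	0	0	0	0	0	0	0	0	0
mS27	0	0	1064.4	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	1395.4	0	0	0	0	904.9	0	0	0	0	688.7
mS29	0	0	0	0	0	0	0	0	0	0	0	0	0	1369.7	0	0	0	0	0	0	0	0	1369.4	0	0	0	0	966.1	617	0
mS31	0	0	0	0	0	0	0	0	0	0	0	0	0	1012.3	0	0	0	0	0	0	0	1369.4	0	0	0	747.7	0	0	261.3	0
mS33	0	0	0	0	0	0	0	0	0	0	661.8	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0
mS34	0	0	471.8	0	0	0	0	0	0	0	0	0	0	0	0	0	735.5	0	0	0	904.9	0	0	0	0	0	0	0	0	0
mS35	0	0	0	0	0	1296.7	0	0	0	0	865	0	0	0	0	0	0	0	0	0	0	0	747.7	0	0	0	0	0	0	0
mS37	0	0	0	0	0	0	0	0	625	0	0	1369.6	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0
mS38	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	966.1	0	0	0	0	0	0	0	0
mS39	0	0	0	0	0	0	0	0	0	0	0	0	0	0	979.3	0	0	0	0	0	0	617	261.3	0	0	0	0	0	0	0
mS40	0	0	1342.5	0	0	0	0	0	0	0	1291	0	0	0	0	588.6	761.9	0	0	0	688.7	0	0	0	0	0	0	0	0	0
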
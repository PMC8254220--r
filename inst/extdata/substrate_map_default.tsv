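# Default CAZyme family -> polysaccharide substrate map.
# GH5 and GH3 carry their published poly-specific assignments
# (GH5: cellulose, mannan, xylan, xyloglucan; GH3: beta-glucan, cellulose,
# xylan, xyloglucan); the remaining rows are canonical family-level substrate
# assignments chosen by this package. Parent family names match all
# subfamilies. CBMs are non-catalytic and deliberately unmapped.
family	category
GH5	cellulose
GH5	mannan
GH5	xylan
GH5	xyloglucan
GH3	beta-glucan
GH3	cellulose
GH3	xylan
GH3	xyloglucan
GH10	xylan
GH11	xylan
GH30	xylan
GH43	xylan
GH51	xylan
GH62	xylan
GH67	xylan
GH115	xylan
CE1	xylan
CE4	xylan
CE4	chitin
CE5	xylan
CE15	xylan
AA14	xylan
GH6	cellulose
GH7	cellulose
GH9	cellulose
GH12	cellulose
GH45	cellulose
AA9	cellulose
GH1	beta-glucan
GH16	beta-glucan
GH17	beta-glucan
GH55	beta-glucan
GH64	beta-glucan
GH81	beta-glucan
GH18	chitin
GH19	chitin
GH20	chitin
GH75	chitin
CE9	chitin
GH26	mannan
GH27	mannan
GH36	mannan
GH38	mannan
GH76	mannan
GH28	pectin
GH78	pectin
GH88	pectin
GH105	pectin
PL1	pectin
PL3	pectin
PL4	pectin
PL9	pectin
CE8	pectin
CE12	pectin
GH13	starch
GH14	starch
GH15	starch
GH31	starch
GH133	starch
AA1	lignin
AA2	lignin
GH74	xyloglucan
GH29	xyloglucan
GH95	xyloglucan
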
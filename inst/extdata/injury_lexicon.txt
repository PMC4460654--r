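abdomen
abrasion
accident
ankle
appliance
approximately
armchair
assault
asthma
athletic
avulsion
backyard
balcony
bandage
barbecue
baseball
basketball
bathroom
bathtub
bedroom
bicycle
bitten
blade
bleeding
blister
blunt
boiling
bottle
boulder
breathing
bricks
bruise
building
bumper
burnt
bystander
cabinet
campfire
carpet
cattle
ceiling
cement
chainsaw
chemical
chest
choking
cleaner
cliff
clothing
collision
concrete
concussion
contusion
cooker
corrosive
cricket
crushed
cupboard
curtain
cyclist
deformity
detergent
diesel
dislocation
dizziness
doorway
dressing
driveway
drowning
elbow
electric
engine
escalator
exhaust
explosion
fallen
farmyard
faucet
fence
fireworks
fishing
flame
floorboard
football
footpath
forehead
forklift
fracture
fragment
freezer
friction
frostbite
fumes
furnace
furniture
garage
garden
gasoline
glassware
gravel
grinder
gutter
gymnasium
hallway
hammer
handlebar
handrail
harness
hazard
headache
heater
helmet
highway
horse
hospital
hydraulic
ignition
incision
infection
inflamed
ingestion
inhalation
insect
intersection
intoxication
irritation
jagged
jammed
jogging
kerosene
kettle
kitchen
kneecap
ladder
laceration
laundry
lawnmower
lighter
lightning
machinery
mattress
medication
microwave
mixer
motorbike
motorcycle
motorist
mower
needle
neighbour
numbness
nursery
oven
overdose
paddock
painful
parked
passenger
patient
pavement
pedal
pedestrian
pesticide
petrol
playground
pliers
poisoning
pollen
porch
propane
puncture
quadbike
radiator
railing
rash
razor
rearend
reversing
roadway
rollerblade
roundabout
rubbish
rugby
saucepan
scaffold
scald
scalp
scissors
scooter
scratch
seatbelt
shattered
shoulder
shovel
shower
sidewalk
skateboard
skidded
slippery
smoke
soccer
socket
solvent
spanner
spider
spillage
splinter
sporting
sprain
sprinkler
staircase
steering
stepladder
sting
stomach
stove
stubbed
stumbled
sunburn
surgery
swelling
swimming
swing
syringe
tackle
tendon
thigh
thumb
timber
toaster
toddler
tongs
toolbox
torso
tractor
trailer
trampoline
trapped
treadmill
tripped
trolley
tumble
twisted
unconscious
utensil
vapour
vehicle
veranda
vomiting
wading
walkway
wardrobe
warehouse
washing
wasp
weakness
welding
wheelbarrow
wheelchair
windscreen
workbench
workshop
wound
wrench
wrist
yardwork
abattoir
acid
aerosol
airbag
alcohol
allergic
ambulance
amputation
anaphylaxis
antiseptic
artery
attacked
awning
axe
barbed
battery
beehive
blowtorch
bollard
bonfire
bookshelf
breakage
briefcase
bulldozer
bungee
burner
buttock
camping
canoe
caravan
cardboard
cartridge
carving
cauldron
chimney
chisel
circular
clamp
clippers
collapsed
compressor
conveyor
corridor
crane
crowbar
crutches
dagger
decking
digger
dinghy
dishwasher
dryer
dumbbell
earthmover
electrocution
embankment
entangled
eyebrow
firearm
fireplace
firepit
flooring
forearm
fryer
generator
goalpost
golfclub
grandstand
grater
griddle
groin
guardrail
gunshot
gymnast
hailstone
hatchet
haystack
hedgetrimmer
hoist
horsebox
hotplate
incinerator
jackhammer
javelin
jetski
kayak
kickboard
knuckle
lathe
lumber
manhole
motorhome
mulcher
nailgun
netball
oilspill
outboard
overpass
paddling
pallet
paving
pickaxe
pitchfork
polisher
pothole
pressure
projectile
pruner
quarry
racquet
rafter
rake
rodeo
rooftop
rototiller
saddle
sander
sawmill
scooterist
scythe
shears
shredder
skylight
sledgehammer
snorkel
softball
soldering
spade
spearfishing
spindle
sprocket
stairwell
stockyard
strimmer
surfboard
tarpaulin
telehandler
terrace
thresher
tileroof
towbar
towrope
turbine
tyre
underpass
upholstery
vacuum
vice
volleyball
wakeboard
waterslide
winch
windmill
woodpile
kph
left
right
temperature
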